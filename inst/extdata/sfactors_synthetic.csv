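isotope,source,target,S_mGy_per_MBq_h,ref_mass_kg
Lu177,wholebody,wholebody,1.312e-06,70
Lu177,wholebody,lung,8.651e-08,1
Lu177,wholebody,liver,8.651e-08,1.8
Lu177,wholebody,kidneys,8.651e-08,0.31
Lu177,wholebody,spleen,8.651e-08,0.18
Lu177,wholebody,heart,8.651e-08,0.33
Lu177,wholebody,aorta,8.651e-08,0.1
Lu177,wholebody,red_marrow,8.651e-08,1.1
Lu177,wholebody,tumor,8.651e-08,0.02
Lu177,lung,wholebody,8.651e-08,70
Lu177,lung,lung,8.639e-05,1
Lu177,lung,liver,1.121e-07,1.8
Lu177,lung,kidneys,6.511e-07,0.31
Lu177,lung,spleen,1.121e-06,0.18
Lu177,lung,heart,6.117e-07,0.33
Lu177,lung,aorta,2.019e-06,0.1
Lu177,lung,red_marrow,1.835e-07,1.1
Lu177,lung,tumor,0,0.02
Lu177,liver,wholebody,8.651e-08,70
Lu177,liver,lung,2.019e-07,1
Lu177,liver,liver,4.8e-05,1.8
Lu177,liver,kidneys,6.511e-07,0.31
Lu177,liver,spleen,1.121e-06,0.18
Lu177,liver,heart,6.117e-07,0.33
Lu177,liver,aorta,2.019e-06,0.1
Lu177,liver,red_marrow,1.835e-07,1.1
Lu177,liver,tumor,0,0.02
Lu177,kidneys,wholebody,8.651e-08,70
Lu177,kidneys,lung,2.019e-07,1
Lu177,kidneys,liver,1.121e-07,1.8
Lu177,kidneys,kidneys,0.0002787,0.31
Lu177,kidneys,spleen,1.121e-06,0.18
Lu177,kidneys,heart,6.117e-07,0.33
Lu177,kidneys,aorta,2.019e-06,0.1
Lu177,kidneys,red_marrow,1.835e-07,1.1
Lu177,kidneys,tumor,0,0.02
Lu177,spleen,wholebody,8.651e-08,70
Lu177,spleen,lung,2.019e-07,1
Lu177,spleen,liver,1.121e-07,1.8
Lu177,spleen,kidneys,6.511e-07,0.31
Lu177,spleen,spleen,0.00048,0.18
Lu177,spleen,heart,6.117e-07,0.33
Lu177,spleen,aorta,2.019e-06,0.1
Lu177,spleen,red_marrow,1.835e-07,1.1
Lu177,spleen,tumor,0,0.02
Lu177,heart,wholebody,8.651e-08,70
Lu177,heart,lung,2.019e-07,1
Lu177,heart,liver,1.121e-07,1.8
Lu177,heart,kidneys,6.511e-07,0.31
Lu177,heart,spleen,1.121e-06,0.18
Lu177,heart,heart,0.0002618,0.33
Lu177,heart,aorta,2.019e-06,0.1
Lu177,heart,red_marrow,1.835e-07,1.1
Lu177,heart,tumor,0,0.02
Lu177,aorta,wholebody,8.651e-08,70
Lu177,aorta,lung,2.019e-07,1
Lu177,aorta,liver,1.121e-07,1.8
Lu177,aorta,kidneys,6.511e-07,0.31
Lu177,aorta,spleen,1.121e-06,0.18
Lu177,aorta,heart,6.117e-07,0.33
Lu177,aorta,aorta,0.0008639,0.1
Lu177,aorta,red_marrow,1.835e-07,1.1
Lu177,aorta,tumor,0,0.02
Lu177,red_marrow,wholebody,8.651e-08,70
Lu177,red_marrow,lung,2.019e-07,1
Lu177,red_marrow,liver,1.121e-07,1.8
Lu177,red_marrow,kidneys,6.511e-07,0.31
Lu177,red_marrow,spleen,1.121e-06,0.18
Lu177,red_marrow,heart,6.117e-07,0.33
Lu177,red_marrow,aorta,2.019e-06,0.1
Lu177,red_marrow,red_marrow,7.854e-05,1.1
Lu177,red_marrow,tumor,0,0.02
Lu177,tumor,wholebody,8.651e-08,70
Lu177,tumor,lung,0,1
Lu177,tumor,liver,0,1.8
Lu177,tumor,kidneys,0,0.31
Lu177,tumor,spleen,0,0.18
Lu177,tumor,heart,0,0.33
Lu177,tumor,aorta,0,0.1
Lu177,tumor,red_marrow,0,1.1
Lu177,tumor,tumor,0.00432,0.02
In111,wholebody,wholebody,1.448e-06,70
In111,wholebody,lung,1.001e-06,1
In111,wholebody,liver,1.001e-06,1.8
In111,wholebody,kidneys,1.001e-06,0.31
In111,wholebody,spleen,1.001e-06,0.18
In111,wholebody,heart,1.001e-06,0.33
In111,wholebody,aorta,1.001e-06,0.1
In111,wholebody,red_marrow,1.001e-06,1.1
In111,wholebody,tumor,1.001e-06,0.02
In111,lung,wholebody,1.001e-06,70
In111,lung,lung,3.829e-05,1
In111,lung,liver,1.298e-06,1.8
In111,lung,kidneys,7.535e-06,0.31
In111,lung,spleen,1.298e-05,0.18
In111,lung,heart,7.078e-06,0.33
In111,lung,aorta,2.336e-05,0.1
In111,lung,red_marrow,2.123e-06,1.1
In111,lung,tumor,0,0.02
In111,liver,wholebody,1.001e-06,70
In111,liver,lung,2.336e-06,1
In111,liver,liver,2.127e-05,1.8
In111,liver,kidneys,7.535e-06,0.31
In111,liver,spleen,1.298e-05,0.18
In111,liver,heart,7.078e-06,0.33
In111,liver,aorta,2.336e-05,0.1
In111,liver,red_marrow,2.123e-06,1.1
In111,liver,tumor,0,0.02
In111,kidneys,wholebody,1.001e-06,70
In111,kidneys,lung,2.336e-06,1
In111,kidneys,liver,1.298e-06,1.8
In111,kidneys,kidneys,0.0001235,0.31
In111,kidneys,spleen,1.298e-05,0.18
In111,kidneys,heart,7.078e-06,0.33
In111,kidneys,aorta,2.336e-05,0.1
In111,kidneys,red_marrow,2.123e-06,1.1
In111,kidneys,tumor,0,0.02
In111,spleen,wholebody,1.001e-06,70
In111,spleen,lung,2.336e-06,1
In111,spleen,liver,1.298e-06,1.8
In111,spleen,kidneys,7.535e-06,0.31
In111,spleen,spleen,0.0002127,0.18
In111,spleen,heart,7.078e-06,0.33
In111,spleen,aorta,2.336e-05,0.1
In111,spleen,red_marrow,2.123e-06,1.1
In111,spleen,tumor,0,0.02
In111,heart,wholebody,1.001e-06,70
In111,heart,lung,2.336e-06,1
In111,heart,liver,1.298e-06,1.8
In111,heart,kidneys,7.535e-06,0.31
In111,heart,spleen,1.298e-05,0.18
In111,heart,heart,0.000116,0.33
In111,heart,aorta,2.336e-05,0.1
In111,heart,red_marrow,2.123e-06,1.1
In111,heart,tumor,0,0.02
In111,aorta,wholebody,1.001e-06,70
In111,aorta,lung,2.336e-06,1
In111,aorta,liver,1.298e-06,1.8
In111,aorta,kidneys,7.535e-06,0.31
In111,aorta,spleen,1.298e-05,0.18
In111,aorta,heart,7.078e-06,0.33
In111,aorta,aorta,0.0003829,0.1
In111,aorta,red_marrow,2.123e-06,1.1
In111,aorta,tumor,0,0.02
In111,red_marrow,wholebody,1.001e-06,70
In111,red_marrow,lung,2.336e-06,1
In111,red_marrow,liver,1.298e-06,1.8
In111,red_marrow,kidneys,7.535e-06,0.31
In111,red_marrow,spleen,1.298e-05,0.18
In111,red_marrow,heart,7.078e-06,0.33
In111,red_marrow,aorta,2.336e-05,0.1
In111,red_marrow,red_marrow,3.481e-05,1.1
In111,red_marrow,tumor,0,0.02
In111,tumor,wholebody,1.001e-06,70
In111,tumor,lung,0,1
In111,tumor,liver,0,1.8
In111,tumor,kidneys,0,0.31
In111,tumor,spleen,0,0.18
In111,tumor,heart,0,0.33
In111,tumor,aorta,0,0.1
In111,tumor,red_marrow,0,1.1
In111,tumor,tumor,0.001915,0.02
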