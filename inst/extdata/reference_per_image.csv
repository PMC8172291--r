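dataset,image,ACC,Se,Sp,AUC
DRIVE,01_test,0.946,0.928,0.947,0.938
DRIVE,02_test,0.952,0.914,0.956,0.935
DRIVE,03_test,0.955,0.817,0.970,0.894
DRIVE,04_test,0.959,0.868,0.968,0.918
DRIVE,05_test,0.958,0.838,0.971,0.904
DRIVE,06_test,0.958,0.811,0.973,0.892
DRIVE,07_test,0.954,0.851,0.964,0.907
DRIVE,08_test,0.958,0.820,0.971,0.896
DRIVE,09_test,0.959,0.849,0.969,0.909
DRIVE,10_test,0.957,0.863,0.965,0.914
DRIVE,11_test,0.945,0.870,0.952,0.911
DRIVE,12_test,0.958,0.875,0.966,0.920
DRIVE,13_test,0.953,0.859,0.963,0.911
DRIVE,14_test,0.954,0.901,0.959,0.930
DRIVE,15_test,0.951,0.917,0.954,0.935
DRIVE,16_test,0.954,0.889,0.961,0.925
DRIVE,17_test,0.958,0.845,0.968,0.907
DRIVE,18_test,0.954,0.913,0.958,0.935
DRIVE,19_test,0.954,0.937,0.956,0.946
DRIVE,20_test,0.955,0.925,0.957,0.941
STARE,im0002,0.972,0.839,0.981,0.910
STARE,im0077,0.967,0.966,0.961,0.964
STARE,im0163,0.961,0.976,0.960,0.968
STARE,im0255,0.970,0.872,0.979,0.926
STARE,im0291,0.980,0.798,0.990,0.894
CHASE_DB1,11L,0.946,0.937,0.947,0.942
CHASE_DB1,11R,0.942,0.950,0.942,0.946
CHASE_DB1,12L,0.953,0.878,0.959,0.919
CHASE_DB1,12R,0.958,0.872,0.965,0.918
CHASE_DB1,13L,0.958,0.884,0.963,0.923
CHASE_DB1,13R,0.956,0.850,0.963,0.907
CHASE_DB1,14L,0.970,0.895,0.968,0.931
CHASE_DB1,14R,0.966,0.867,0.971,0.919
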