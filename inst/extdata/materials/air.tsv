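energy_keV	total	photoelectric	incoherent	coherent
5.000000e+00	4.027000e+01	3.925969e+01	1.961692e-01	8.141380e-01
5.375243e+00	3.246958e+01	3.156925e+01	1.958904e-01	7.044364e-01
5.778648e+00	2.618012e+01	2.537501e+01	1.955919e-01	6.095166e-01
6.000000e+00	2.341000e+01	2.264920e+01	1.954286e-01	5.653736e-01
6.212327e+00	2.110233e+01	2.037967e+01	1.952722e-01	5.273869e-01
6.678554e+00	1.700363e+01	1.635237e+01	1.949301e-01	4.563238e-01
7.179771e+00	1.370102e+01	1.311162e+01	1.945641e-01	3.948361e-01
7.718602e+00	1.103987e+01	1.050407e+01	1.941726e-01	3.416337e-01
8.000000e+00	9.921000e+00	9.409008e+00	1.939690e-01	3.180227e-01
8.297873e+00	8.902037e+00	8.412682e+00	1.937540e-01	2.956000e-01
8.920617e+00	7.183269e+00	6.734193e+00	1.933067e-01	2.557692e-01
9.590097e+00	5.796353e+00	5.382219e+00	1.928288e-01	2.213054e-01
1.000000e+01	5.120000e+00	4.723928e+00	1.925377e-01	2.035345e-01
1.030982e+01	4.693982e+00	4.310178e+00	1.923185e-01	1.914855e-01
1.108356e+01	3.819965e+00	3.462508e+00	1.917738e-01	1.656836e-01
1.191536e+01	3.108690e+00	2.774139e+00	1.911928e-01	1.433585e-01
1.280960e+01	2.529854e+00	2.215239e+00	1.905733e-01	1.240415e-01
1.377094e+01	2.058796e+00	1.761555e+00	1.899133e-01	1.073275e-01
1.480443e+01	1.675450e+00	1.393374e+00	1.892104e-01	9.286556e-02
1.500000e+01	1.614000e+00	1.334462e+00	1.890782e-01	9.045978e-02
1.591548e+01	1.388763e+00	1.119948e+00	1.884624e-01	8.035232e-02
1.710992e+01	1.155826e+00	8.986338e-01	1.876670e-01	6.952520e-02
1.839399e+01	9.619595e-01	7.149807e-01	1.868218e-01	6.015698e-02
1.977444e+01	8.006102e-01	5.626347e-01	1.859244e-01	5.205108e-02
2.000000e+01	7.779000e-01	5.412376e-01	1.857788e-01	5.088362e-02
2.125848e+01	6.909185e-01	4.609088e-01	1.849723e-01	4.503742e-02
2.285390e+01	6.002861e-01	3.773541e-01	1.839632e-01	3.896883e-02
2.456906e+01	5.215426e-01	3.049300e-01	1.828946e-01	3.371795e-02
2.641293e+01	4.531284e-01	2.421895e-01	1.817643e-01	2.917460e-02
2.839518e+01	3.936886e-01	1.878753e-01	1.805698e-01	2.524345e-02
3.000000e+01	3.538000e-01	1.515669e-01	1.796182e-01	2.261494e-02
3.052620e+01	3.463252e-01	1.451741e-01	1.793091e-01	2.184200e-02
3.281715e+01	3.168755e-01	1.199968e-01	1.779799e-01	1.889889e-02
3.528004e+01	2.899301e-01	9.699742e-02	1.765804e-01	1.635234e-02
3.792775e+01	2.652760e-01	7.601841e-02	1.751086e-01	1.414894e-02
4.000000e+01	2.485000e-01	6.179925e-02	1.739798e-01	1.272091e-02
4.077418e+01	2.447310e-01	5.892536e-02	1.735632e-01	1.224243e-02
4.383423e+01	2.310109e-01	4.847537e-02	1.719427e-01	1.059281e-02
4.712393e+01	2.180599e-01	3.864843e-02	1.702460e-01	9.165477e-03
5.000000e+01	2.080000e-01	3.105883e-02	1.687998e-01	8.141380e-03
5.066051e+01	2.064523e-01	3.004940e-02	1.684724e-01	7.930469e-03
5.446252e+01	1.981226e-01	2.463920e-02	1.666215e-01	6.861872e-03
5.854985e+01	1.901289e-01	1.949846e-02	1.646932e-01	5.937265e-03
6.000000e+01	1.875000e-01	1.782244e-02	1.640238e-01	5.653736e-03
6.294394e+01	1.837729e-01	1.594778e-02	1.626879e-01	5.137244e-03
6.766780e+01	1.782821e-01	1.323081e-02	1.606063e-01	4.445023e-03
7.274617e+01	1.729554e-01	1.065966e-02	1.584497e-01	3.846075e-03
7.820567e+01	1.677879e-01	8.240292e-03	1.562197e-01	3.327833e-03
8.000000e+01	1.662000e-01	7.513823e-03	1.555060e-01	3.180227e-03
8.407490e+01	1.634263e-01	6.628287e-03	1.539186e-01	2.879422e-03
9.038461e+01	1.594688e-01	5.428417e-03	1.515489e-01	2.491432e-03
9.716785e+01	1.556071e-01	4.337540e-03	1.491138e-01	2.155722e-03
1.000000e+02	1.541000e-01	3.934976e-03	1.481297e-01	2.035345e-03
1.044602e+02	1.519936e-01	3.511474e-03	1.466168e-01	1.865248e-03
1.122998e+02	1.485635e-01	2.887616e-03	1.440620e-01	1.613914e-03
1.207277e+02	1.452108e-01	2.360801e-03	1.414536e-01	1.396446e-03
1.297881e+02	1.419338e-01	1.929101e-03	1.387964e-01	1.208281e-03
1.395286e+02	1.387308e-01	1.589707e-03	1.360956e-01	1.045470e-03
1.500000e+02	1.356000e-01	1.339064e-03	1.333563e-01	9.045978e-04
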