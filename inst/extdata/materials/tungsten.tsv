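energy_keV	total	photoelectric	incoherent	coherent
5.000000e+00	7.750000e+02	7.680929e+02	1.581725e-01	6.748954e+00
5.375243e+00	6.273349e+02	6.213374e+02	1.579477e-01	5.839562e+00
5.778648e+00	5.078052e+02	5.025948e+02	1.577069e-01	5.052706e+00
6.000000e+00	4.550000e+02	4.501557e+02	1.575753e-01	4.686774e+00
6.212327e+00	4.099350e+02	4.054056e+02	1.574492e-01	4.371876e+00
6.678554e+00	3.299570e+02	3.260170e+02	1.571734e-01	3.782785e+00
7.179771e+00	2.655826e+02	2.621527e+02	1.568782e-01	3.273071e+00
7.718602e+00	2.137676e+02	2.107790e+02	1.565626e-01	2.832039e+00
8.000000e+00	1.920000e+02	1.892073e+02	1.563984e-01	2.636310e+00
8.297873e+00	1.716543e+02	1.690476e+02	1.562251e-01	2.450434e+00
8.920617e+00	1.375178e+02	1.352417e+02	1.558644e-01	2.120248e+00
9.590097e+00	1.101699e+02	1.081799e+02	1.554790e-01	1.834554e+00
1.000000e+01	9.691000e+01	9.506752e+01	1.552443e-01	1.687239e+00
1.020570e+01	9.100000e+01	8.922496e+01	1.551269e-01	1.619910e+00
1.020770e+01	2.240000e+02	2.222256e+02	1.551258e-01	1.619275e+00
1.100000e+01	1.820000e+02	1.804509e+02	1.546757e-01	1.394412e+00
1.154300e+01	1.585000e+02	1.570793e+02	1.543692e-01	1.266307e+00
1.154500e+01	2.180000e+02	2.165798e+02	1.543681e-01	1.265869e+00
1.191536e+01	1.989923e+02	1.976498e+02	1.541599e-01	1.188398e+00
1.209880e+01	1.904000e+02	1.890933e+02	1.540571e-01	1.152635e+00
1.210080e+01	2.330000e+02	2.316937e+02	1.540560e-01	1.152254e+00
1.280960e+01	1.981491e+02	1.969672e+02	1.536605e-01	1.028266e+00
1.300000e+01	1.900000e+02	1.888481e+02	1.535547e-01	9.983660e-01
1.377094e+01	1.675353e+02	1.664925e+02	1.531283e-01	8.897118e-01
1.480443e+01	1.430419e+02	1.421196e+02	1.525615e-01	7.698270e-01
1.500000e+01	1.390000e+02	1.380977e+02	1.524549e-01	7.498838e-01
1.591548e+01	1.191341e+02	1.183160e+02	1.519584e-01	6.660961e-01
1.710992e+01	9.867787e+01	9.795021e+01	1.513171e-01	5.763426e-01
1.839399e+01	8.173412e+01	8.108480e+01	1.506356e-01	4.986829e-01
1.977444e+01	6.769975e+01	6.711835e+01	1.499120e-01	4.314875e-01
2.000000e+01	6.573000e+01	6.515840e+01	1.497946e-01	4.218097e-01
2.125848e+01	5.602180e+01	5.549931e+01	1.491443e-01	3.733464e-01
2.285390e+01	4.635005e+01	4.587868e+01	1.483307e-01	3.230396e-01
2.456906e+01	3.834806e+01	3.792108e+01	1.474691e-01	2.795114e-01
2.641293e+01	3.172755e+01	3.133914e+01	1.465577e-01	2.418485e-01
2.839518e+01	2.625002e+01	2.589516e+01	1.455946e-01	2.092604e-01
3.000000e+01	2.273000e+01	2.239770e+01	1.448273e-01	1.874710e-01
3.052620e+01	2.171442e+01	2.138878e+01	1.445780e-01	1.810635e-01
3.281715e+01	1.795275e+01	1.765258e+01	1.435063e-01	1.566660e-01
3.528004e+01	1.484273e+01	1.456479e+01	1.423778e-01	1.355559e-01
3.792775e+01	1.227147e+01	1.201299e+01	1.411912e-01	1.172903e-01
4.000000e+01	1.067000e+01	1.042427e+01	1.402810e-01	1.054524e-01
4.077418e+01	1.014771e+01	9.906279e+00	1.399451e-01	1.014860e-01
4.383423e+01	8.396262e+00	8.169812e+00	1.386384e-01	8.781118e-02
4.712393e+01	6.947106e+00	6.733857e+00	1.372704e-01	7.597900e-02
5.000000e+01	5.949000e+00	5.745406e+00	1.361043e-01	6.748954e-02
5.066051e+01	5.750532e+00	5.548950e+00	1.358404e-01	6.574116e-02
5.446252e+01	4.769274e+00	4.578043e+00	1.343480e-01	5.688282e-02
5.854985e+01	3.955455e+00	3.773444e+00	1.327932e-01	4.921811e-02
6.000000e+01	3.713000e+00	3.533879e+00	1.322534e-01	4.686774e-02
6.294394e+01	3.286852e+00	3.113089e+00	1.311762e-01	4.258618e-02
6.766780e+01	2.733962e+00	2.567616e+00	1.294979e-01	3.684788e-02
6.952400e+01	2.552000e+00	2.388239e+00	1.288546e-01	3.490656e-02
6.952600e+01	1.123000e+01	1.106624e+01	1.288539e-01	3.490455e-02
7.274617e+01	9.988248e+00	9.828606e+00	1.277590e-01	3.188278e-02
7.820567e+01	8.282258e+00	8.128710e+00	1.259609e-01	2.758672e-02
8.000000e+01	7.810000e+00	7.658251e+00	1.253854e-01	2.636310e-02
8.407490e+01	6.886525e+00	6.738550e+00	1.241055e-01	2.386953e-02
9.038461e+01	5.733182e+00	5.590334e+00	1.221948e-01	2.065321e-02
9.716785e+01	4.772999e+00	4.634898e+00	1.202314e-01	1.787028e-02
1.000000e+02	4.438000e+00	4.301690e+00	1.194379e-01	1.687239e-02
1.044602e+02	3.971428e+00	3.837747e+00	1.182181e-01	1.546234e-02
1.122998e+02	3.303267e+00	3.173730e+00	1.161581e-01	1.337885e-02
1.207277e+02	2.747519e+00	2.621888e+00	1.140549e-01	1.157611e-02
1.297881e+02	2.285271e+00	2.163343e+00	1.119124e-01	1.001628e-02
1.395286e+02	1.900793e+00	1.782392e+00	1.097347e-01	8.666629e-03
1.500000e+02	1.581000e+00	1.465975e+00	1.075260e-01	7.498838e-03
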