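energy_keV	total	photoelectric	incoherent	coherent
5.000000e+00	3.950000e+00	3.372368e+00	1.744181e-01	4.032137e-01
5.375243e+00	3.230488e+00	2.707435e+00	1.741702e-01	3.488824e-01
5.778648e+00	2.642038e+00	2.166262e+00	1.739047e-01	3.018720e-01
6.000000e+00	2.380000e+00	1.926231e+00	1.737595e-01	2.800095e-01
6.212327e+00	2.164401e+00	1.729584e+00	1.736205e-01	2.611961e-01
6.678554e+00	1.776326e+00	1.377009e+00	1.733163e-01	2.260010e-01
7.179771e+00	1.457833e+00	1.089294e+00	1.729909e-01	1.955484e-01
7.718602e+00	1.196445e+00	8.546034e-01	1.726428e-01	1.691991e-01
8.000000e+00	1.085000e+00	7.550329e-01	1.724618e-01	1.575054e-01
8.297873e+00	9.967854e-01	6.781145e-01	1.722707e-01	1.464002e-01
8.920617e+00	8.427534e-01	5.442070e-01	1.718729e-01	1.266734e-01
9.590097e+00	7.125237e-01	4.314710e-01	1.714480e-01	1.096047e-01
1.000000e+01	6.466000e-01	3.746074e-01	1.711892e-01	1.008034e-01
1.030982e+01	6.113530e-01	3.455228e-01	1.709943e-01	9.483597e-02
1.108356e+01	5.352485e-01	2.826813e-01	1.705100e-01	8.205723e-02
1.191536e+01	4.686179e-01	2.276241e-01	1.699934e-01	7.100038e-02
1.280960e+01	4.102818e-01	1.794058e-01	1.694426e-01	6.143338e-02
1.377094e+01	3.592077e-01	1.371965e-01	1.688558e-01	5.315550e-02
1.480443e+01	3.144916e-01	1.002678e-01	1.682308e-01	4.599302e-02
1.500000e+01	3.070000e-01	9.408521e-02	1.681133e-01	4.480153e-02
1.591548e+01	2.879962e-01	8.063475e-02	1.675658e-01	3.979566e-02
1.710992e+01	2.663713e-01	6.507935e-02	1.668586e-01	3.443337e-02
1.839399e+01	2.463701e-01	5.046945e-02	1.661071e-01	2.979362e-02
1.977444e+01	2.278708e-01	3.678262e-02	1.653091e-01	2.577906e-02
2.000000e+01	2.251000e-01	3.471942e-02	1.651797e-01	2.520086e-02
2.125848e+01	2.175054e-01	3.073733e-02	1.644626e-01	2.230544e-02
2.285390e+01	2.088306e-01	2.596534e-02	1.635654e-01	1.929988e-02
2.456906e+01	2.005018e-01	2.118719e-02	1.626154e-01	1.669931e-02
2.641293e+01	1.925052e-01	1.644575e-02	1.616103e-01	1.444915e-02
2.839518e+01	1.848275e-01	1.177703e-02	1.605483e-01	1.250219e-02
3.000000e+01	1.792000e-01	8.297433e-03	1.597022e-01	1.120038e-02
3.052620e+01	1.782425e-01	7.997606e-03	1.594274e-01	1.081757e-02
3.281715e+01	1.743124e-01	6.706864e-03	1.582456e-01	9.359950e-03
3.528004e+01	1.704689e-01	5.368942e-03	1.570012e-01	8.098737e-03
3.792775e+01	1.667101e-01	4.009981e-03	1.556927e-01	7.007467e-03
4.000000e+01	1.640000e-01	3.010763e-03	1.546890e-01	6.300215e-03
4.077418e+01	1.632429e-01	2.861061e-03	1.543186e-01	6.063241e-03
4.383423e+01	1.604161e-01	2.292100e-03	1.528777e-01	5.246246e-03
4.712393e+01	1.576382e-01	1.729708e-03	1.513692e-01	4.539337e-03
5.000000e+01	1.554000e-01	1.284527e-03	1.500833e-01	4.032137e-03
5.066051e+01	1.549527e-01	1.232769e-03	1.497923e-01	3.927681e-03
5.446252e+01	1.525093e-01	9.642974e-04	1.481466e-01	3.398443e-03
5.854985e+01	1.501044e-01	7.318439e-04	1.464321e-01	2.940517e-03
6.000000e+01	1.493000e-01	6.629835e-04	1.458369e-01	2.800095e-03
6.294394e+01	1.477273e-01	5.338817e-04	1.446491e-01	2.544295e-03
6.766780e+01	1.453826e-01	3.828400e-04	1.427983e-01	2.201462e-03
7.274617e+01	1.430752e-01	2.895260e-04	1.408808e-01	1.904825e-03
7.820567e+01	1.408044e-01	2.580724e-04	1.388982e-01	1.648158e-03
8.000000e+01	1.401000e-01	2.614372e-04	1.382635e-01	1.575054e-03
8.407490e+01	1.384407e-01	1.624853e-04	1.368522e-01	1.426076e-03
9.038461e+01	1.360589e-01	7.977678e-05	1.347452e-01	1.233918e-03
9.716785e+01	1.337181e-01	7.033548e-05	1.325801e-01	1.067653e-03
1.000000e+02	1.328000e-01	8.685018e-05	1.317051e-01	1.008034e-03
1.044602e+02	1.312411e-01	1.312411e-05	1.303042e-01	9.237914e-04
1.122998e+02	1.286961e-01	1.286961e-05	1.278839e-01	7.993145e-04
1.207277e+02	1.262004e-01	1.262004e-05	1.254962e-01	6.916104e-04
1.297881e+02	1.237531e-01	1.237531e-05	1.231423e-01	5.984188e-04
1.395286e+02	1.213533e-01	1.213533e-05	1.208234e-01	5.177845e-04
1.500000e+02	1.190000e-01	1.190000e-05	1.185401e-01	4.480153e-04
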