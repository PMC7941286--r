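energy_keV	total	photoelectric	incoherent	coherent
5.000000e+00	4.258000e+01	4.153027e+01	2.181326e-01	8.316000e-01
5.375243e+00	3.426991e+01	3.333254e+01	2.178226e-01	7.195455e-01
5.778648e+00	2.758164e+01	2.674156e+01	2.174906e-01	6.225898e-01
6.000000e+00	2.464000e+01	2.384519e+01	2.173090e-01	5.775000e-01
6.212327e+00	2.219244e+01	2.143660e+01	2.171352e-01	5.386986e-01
6.678554e+00	1.785080e+01	1.716793e+01	2.167548e-01	4.661113e-01
7.179771e+00	1.435854e+01	1.373889e+01	2.163478e-01	4.033048e-01
7.718602e+00	1.154949e+01	1.098462e+01	2.159124e-01	3.489612e-01
8.000000e+00	1.037000e+01	9.829470e+00	2.156860e-01	3.248437e-01
8.297873e+00	9.298438e+00	8.781051e+00	2.154470e-01	3.019402e-01
8.920617e+00	7.492790e+00	7.016586e+00	2.149496e-01	2.612550e-01
9.590097e+00	6.037778e+00	5.597308e+00	2.144182e-01	2.260521e-01
1.000000e+01	5.329000e+00	4.907006e+00	2.140945e-01	2.079000e-01
1.030982e+01	4.884082e+00	4.474639e+00	2.138507e-01	1.955925e-01
1.108356e+01	3.971757e+00	3.589275e+00	2.132451e-01	1.692373e-01
1.191536e+01	3.229850e+00	2.870818e+00	2.125990e-01	1.464333e-01
1.280960e+01	2.626528e+00	2.287916e+00	2.119102e-01	1.267020e-01
1.377094e+01	2.135904e+00	1.815099e+00	2.111762e-01	1.096295e-01
1.480443e+01	1.736927e+00	1.431675e+00	2.103947e-01	9.485738e-02
1.500000e+01	1.673000e+00	1.370352e+00	2.102476e-01	9.240000e-02
1.591548e+01	1.440727e+00	1.149089e+00	2.095629e-01	8.207576e-02
1.710992e+01	1.200293e+00	9.205986e-01	2.086785e-01	7.101640e-02
1.839399e+01	9.999840e-01	7.307981e-01	2.077386e-01	6.144725e-02
1.977444e+01	8.331029e-01	5.731947e-01	2.067407e-01	5.316750e-02
2.000000e+01	8.096000e-01	5.510461e-01	2.065789e-01	5.197500e-02
2.125848e+01	7.212254e-01	4.695400e-01	2.056820e-01	4.600341e-02
2.285390e+01	6.288415e-01	3.844769e-01	2.045600e-01	3.980465e-02
2.456906e+01	5.482913e-01	3.104783e-01	2.033718e-01	3.444114e-02
2.641293e+01	4.780590e-01	2.461437e-01	2.021149e-01	2.980035e-02
2.839518e+01	4.168229e-01	1.902514e-01	2.007867e-01	2.578488e-02
3.000000e+01	3.756000e-01	1.527715e-01	1.997285e-01	2.310000e-02
3.052620e+01	3.680397e-01	1.463445e-01	1.993848e-01	2.231048e-02
3.281715e+01	3.381756e-01	1.209646e-01	1.979068e-01	1.930424e-02
3.528004e+01	3.107348e-01	9.768117e-02	1.963505e-01	1.670308e-02
3.792775e+01	2.855206e-01	7.635414e-02	1.947140e-01	1.445241e-02
4.000000e+01	2.683000e-01	6.184738e-02	1.934589e-01	1.299375e-02
4.077418e+01	2.644648e-01	5.896419e-02	1.929956e-01	1.250501e-02
4.383423e+01	2.504743e-01	4.846065e-02	1.911936e-01	1.082001e-02
4.712393e+01	2.372239e-01	3.855485e-02	1.893070e-01	9.362063e-03
5.000000e+01	2.269000e-01	3.088515e-02	1.876989e-01	8.316000e-03
5.066051e+01	2.253193e-01	2.988395e-02	1.873348e-01	8.100565e-03
5.446252e+01	2.167990e-01	2.451332e-02	1.852767e-01	7.009049e-03
5.854985e+01	2.086010e-01	1.940386e-02	1.831325e-01	6.064610e-03
6.000000e+01	2.059000e-01	1.773685e-02	1.823882e-01	5.775000e-03
6.294394e+01	2.020257e-01	1.587562e-02	1.809026e-01	5.247430e-03
6.766780e+01	1.963103e-01	1.318194e-02	1.785880e-01	4.540361e-03
7.274617e+01	1.907566e-01	1.063810e-02	1.761899e-01	3.928567e-03
7.820567e+01	1.853600e-01	8.250498e-03	1.737103e-01	3.399210e-03
8.000000e+01	1.837000e-01	7.534952e-03	1.729166e-01	3.248438e-03
8.407490e+01	1.807225e-01	6.629783e-03	1.711515e-01	2.941181e-03
9.038461e+01	1.764716e-01	5.410207e-03	1.685166e-01	2.544870e-03
9.716785e+01	1.723208e-01	4.309981e-03	1.658088e-01	2.201959e-03
1.000000e+02	1.707000e-01	3.906518e-03	1.647145e-01	2.079000e-03
1.044602e+02	1.684019e-01	3.464431e-03	1.630323e-01	1.905255e-03
1.122998e+02	1.646588e-01	2.818952e-03	1.601913e-01	1.648530e-03
1.207277e+02	1.609989e-01	2.281572e-03	1.572909e-01	1.426398e-03
1.297881e+02	1.574203e-01	1.849828e-03	1.543363e-01	1.234197e-03
1.395286e+02	1.539213e-01	1.520330e-03	1.513330e-01	1.067894e-03
1.500000e+02	1.505000e-01	1.288903e-03	1.482871e-01	9.240000e-04
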