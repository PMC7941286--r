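energy_keV	total	photoelectric	incoherent	coherent
5.000000e+00	1.934000e+02	1.917912e+02	1.893393e-01	1.419412e+00
5.375243e+00	1.575067e+02	1.560894e+02	1.890702e-01	1.228153e+00
5.778648e+00	1.282748e+02	1.270233e+02	1.887821e-01	1.062664e+00
6.000000e+00	1.153000e+02	1.141257e+02	1.886244e-01	9.857029e-01
6.212327e+00	1.043064e+02	1.031984e+02	1.884736e-01	9.194748e-01
6.678554e+00	8.467454e+01	8.369082e+01	1.881434e-01	7.955796e-01
7.179771e+00	6.873769e+01	6.786152e+01	1.877901e-01	6.883787e-01
7.718602e+00	5.580036e+01	5.501732e+01	1.874122e-01	5.956226e-01
8.000000e+00	5.033000e+01	4.958833e+01	1.872157e-01	5.544579e-01
8.297873e+00	4.523330e+01	4.453092e+01	1.870082e-01	5.153650e-01
8.920617e+00	3.661605e+01	3.598355e+01	1.865764e-01	4.459218e-01
9.590097e+00	2.964045e+01	2.906850e+01	1.861152e-01	3.858358e-01
1.000000e+01	2.623000e+01	2.568931e+01	1.858342e-01	3.548530e-01
1.030982e+01	2.397762e+01	2.345816e+01	1.856226e-01	3.338461e-01
1.108356e+01	1.937881e+01	1.890486e+01	1.850969e-01	2.888618e-01
1.191536e+01	1.566204e+01	1.522756e+01	1.845362e-01	2.499389e-01
1.280960e+01	1.265812e+01	1.225793e+01	1.839383e-01	2.162607e-01
1.377094e+01	1.023035e+01	9.859927e+00	1.833012e-01	1.871205e-01
1.480443e+01	8.268210e+00	7.923680e+00	1.826228e-01	1.619068e-01
1.500000e+01	7.955000e+00	7.614792e+00	1.824952e-01	1.577125e-01
1.591548e+01	6.694083e+00	6.372092e+00	1.819008e-01	1.400906e-01
1.710992e+01	5.421741e+00	5.119394e+00	1.811331e-01	1.212140e-01
1.839399e+01	4.391232e+00	4.106034e+00	1.803173e-01	1.048809e-01
1.977444e+01	3.556592e+00	3.286392e+00	1.794511e-01	9.074867e-02
2.000000e+01	3.441000e+00	3.172976e+00	1.793107e-01	8.871326e-02
2.125848e+01	2.909275e+00	2.652222e+00	1.785322e-01	7.852068e-02
2.285390e+01	2.384159e+00	2.138660e+00	1.775583e-01	6.794036e-02
2.456906e+01	1.953825e+00	1.718512e+00	1.765269e-01	5.878569e-02
2.641293e+01	1.601165e+00	1.374865e+00	1.754359e-01	5.086457e-02
2.839518e+01	1.312159e+00	1.093865e+00	1.742830e-01	4.401079e-02
3.000000e+01	1.128000e+00	9.152074e-01	1.733645e-01	3.942812e-02
3.052620e+01	1.082238e+00	8.710915e-01	1.730662e-01	3.808053e-02
3.281715e+01	9.108933e-01	7.061607e-01	1.717833e-01	3.294934e-02
3.528004e+01	7.666765e-01	5.677344e-01	1.704325e-01	2.850956e-02
3.792775e+01	6.452927e-01	4.516127e-01	1.690120e-01	2.466802e-02
4.000000e+01	5.685000e-01	3.783992e-01	1.679225e-01	2.217832e-02
4.077418e+01	5.476641e-01	3.587996e-01	1.675204e-01	2.134411e-02
4.383423e+01	4.756609e-01	2.912366e-01	1.659562e-01	1.846808e-02
4.712393e+01	4.131243e-01	2.328261e-01	1.643186e-01	1.597959e-02
5.000000e+01	3.681000e-01	1.909831e-01	1.629228e-01	1.419412e-02
5.066051e+01	3.607175e-01	1.842843e-01	1.626068e-01	1.382641e-02
5.446252e+01	3.225902e-01	1.498065e-01	1.608203e-01	1.196336e-02
5.854985e+01	2.884928e-01	1.191822e-01	1.589592e-01	1.035135e-02
6.000000e+01	2.778000e-01	1.096299e-01	1.583131e-01	9.857029e-03
6.294394e+01	2.634024e-01	9.742221e-02	1.570237e-01	8.956549e-03
6.766780e+01	2.430536e-01	8.028937e-02	1.550146e-01	7.749693e-03
7.274617e+01	2.242768e-01	6.463835e-02	1.529330e-01	6.705455e-03
7.820567e+01	2.069506e-01	5.036798e-02	1.507807e-01	5.801924e-03
8.000000e+01	2.018000e-01	4.616363e-02	1.500918e-01	5.544579e-03
8.407490e+01	1.943424e-01	4.076258e-02	1.485597e-01	5.020140e-03
9.038461e+01	1.839701e-01	3.335382e-02	1.462725e-01	4.343698e-03
9.716785e+01	1.741513e-01	2.647066e-02	1.439222e-01	3.758403e-03
1.000000e+02	1.704000e-01	2.387913e-02	1.429723e-01	3.548530e-03
1.044602e+02	1.665501e-01	2.178598e-02	1.415122e-01	3.251974e-03
1.122998e+02	1.603562e-01	1.849620e-02	1.390462e-01	2.813785e-03
1.207277e+02	1.543927e-01	1.542935e-02	1.365287e-01	2.434640e-03
1.297881e+02	1.486509e-01	1.258026e-02	1.339640e-01	2.106582e-03
1.395286e+02	1.431226e-01	9.942688e-03	1.313572e-01	1.822730e-03
1.500000e+02	1.378000e-01	7.509525e-03	1.287134e-01	1.577125e-03
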