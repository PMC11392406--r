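"slice_id","point_index","x","y","z"
1,1,-29.3634,-42.498,-22.4292
1,2,-27.6868,-41.696,-23.4557
1,3,-26.0052,-40.758,-24.3466
1,4,-24.3654,-39.5396,-24.9004
1,5,-22.9443,-37.9811,-24.8589
1,6,-21.968,-36.25,-24.1453
1,7,-21.4296,-34.5588,-22.9879
1,8,-21.1578,-32.9546,-21.6251
1,9,-20.9847,-31.3928,-20.1969
1,10,-20.8673,-29.8579,-18.7349
1,11,-20.9517,-28.4347,-17.165
1,12,-21.4371,-27.2987,-15.4486
1,13,-22.4656,-26.7146,-13.7027
1,14,-23.9124,-26.7763,-12.163
1,15,-25.533,-27.2847,-10.8941
1,16,-27.2003,-28.0092,-9.7977
1,17,-28.8787,-28.8857,-8.8464
1,18,-30.5298,-30.0731,-8.248
1,19,-32.0976,-31.4724,-7.9617
1,20,-33.5424,-33.0251,-7.9709
1,21,-34.8234,-34.6877,-8.2757
1,22,-35.8882,-36.4159,-8.888
1,23,-36.6579,-38.149,-9.8326
1,24,-36.9499,-39.7514,-11.1712
1,25,-36.6472,-41.0291,-12.832
1,26,-35.9749,-42.005,-14.5896
1,27,-35.0248,-42.693,-16.3563
1,28,-33.8525,-43.0988,-18.0766
1,29,-32.4971,-43.2188,-19.7035
1,30,-30.99,-43.0356,-21.1839
2,1,-25.2274,-45.7605,-17.6729
2,2,-23.6191,-44.9804,-18.6463
2,3,-22.009,-44.0337,-19.449
2,4,-20.4612,-42.7961,-19.8808
2,5,-19.1523,-41.2595,-19.7378
2,6,-18.2546,-39.5961,-19.0073
2,7,-17.7478,-37.9769,-17.8895
2,8,-17.4904,-36.4404,-16.5809
2,9,-17.3296,-34.9456,-15.2086
2,10,-17.2614,-33.4969,-13.7814
2,11,-17.4439,-32.1968,-12.2306
2,12,-18.0428,-31.2234,-10.557
2,13,-19.1264,-30.7881,-8.9044
2,14,-20.5496,-30.922,-7.4659
2,15,-22.113,-31.4467,-6.2772
2,16,-23.7141,-32.1608,-5.2433
2,17,-25.3235,-33.0862,-4.4193
2,18,-26.896,-34.2651,-3.8992
2,19,-28.3878,-35.6253,-3.6565
2,20,-29.7608,-37.1247,-3.69
2,21,-30.9711,-38.7265,-4.0101
2,22,-31.9601,-40.3875,-4.6368
2,23,-32.6387,-42.0409,-5.5997
2,24,-32.8093,-43.5297,-6.9549
2,25,-32.4471,-44.7018,-8.5722
2,26,-31.7396,-45.5769,-10.2643
2,27,-30.7716,-46.1688,-11.9512
2,28,-29.599,-46.4875,-13.5815
2,29,-28.2623,-46.5356,-15.113
2,30,-26.7944,-46.3048,-16.5005
3,1,-20.6017,-50.4387,-14.9278
3,2,-18.9109,-49.5319,-15.8612
3,3,-17.2675,-48.2853,-16.3898
3,4,-15.8194,-46.7258,-16.3772
3,5,-14.691,-45.0012,-15.839
3,6,-13.9095,-43.2559,-14.8949
3,7,-13.4325,-41.5704,-13.6752
3,8,-13.1845,-39.9666,-12.2864
3,9,-13.0775,-38.4277,-10.8087
3,10,-13.1923,-37.0131,-9.2141
3,11,-13.6207,-35.8184,-7.5
3,12,-14.4315,-34.9705,-5.7218
3,13,-15.6378,-34.606,-4.0066
3,14,-17.1477,-34.7823,-2.516
3,15,-18.8039,-35.4026,-1.3235
3,16,-20.4947,-36.2808,-0.3604
3,17,-22.1732,-37.3956,0.3437
3,18,-23.7885,-38.7297,0.7502
3,19,-25.2817,-40.252,0.8262
3,20,-26.5867,-41.9161,0.5466
3,21,-27.6347,-43.6579,-0.0987
3,22,-28.3633,-45.3969,-1.0949
3,23,-28.7328,-47.0459,-2.3959
3,24,-28.7397,-48.5299,-3.9276
3,25,-28.3701,-49.7694,-5.623
3,26,-27.6436,-50.7036,-7.3972
3,27,-26.6087,-51.3012,-9.1642
3,28,-25.3265,-51.5565,-10.8503
3,29,-23.8597,-51.4818,-12.3986
3,30,-22.2671,-51.0995,-13.7673
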