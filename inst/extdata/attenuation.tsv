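# Mass attenuation (mu_rho) and mass energy-absorption (muen_rho)
# coefficients, cm^2/g, on a 17-point log energy grid, 20-2000 keV.
# Values compiled from standard photon cross-section tabulations (NIST-style)
# to ~1-2%; the Cerrobend alloy curve is a smooth, K-edge-free monotone
# approximation (K-edge structure is deliberately not modeled).
material	energy_kev	mu_rho	muen_rho
water	20	0.8096	0.5503
water	30	0.3756	0.1557
water	40	0.2683	0.0695
water	50	0.2269	0.04223
water	60	0.2059	0.03190
water	80	0.1837	0.02597
water	100	0.1707	0.02546
water	140	0.1538	0.02720
water	200	0.1370	0.02967
water	300	0.1186	0.03192
water	500	0.09687	0.03299
water	662	0.08594	0.03290
water	800	0.07865	0.03206
water	1000	0.07072	0.03103
water	1250	0.06323	0.02965
water	1500	0.05754	0.02833
water	2000	0.04942	0.02608
air	20	0.7779	0.5389
air	30	0.3538	0.1537
air	40	0.2485	0.06833
air	50	0.2080	0.04098
air	60	0.1875	0.03041
air	80	0.1662	0.02407
air	100	0.1541	0.02325
air	140	0.1388	0.02470
air	200	0.1233	0.02672
air	300	0.1067	0.02872
air	500	0.08712	0.02966
air	662	0.07730	0.02960
air	800	0.07074	0.02882
air	1000	0.06358	0.02789
air	1250	0.05687	0.02666
air	1500	0.05175	0.02547
air	2000	0.04447	0.02345
solid_water	20	0.8056	0.5475
solid_water	30	0.3737	0.1549
solid_water	40	0.2670	0.06915
solid_water	50	0.2258	0.04202
solid_water	60	0.2049	0.03174
solid_water	80	0.1828	0.02584
solid_water	100	0.1698	0.02533
solid_water	140	0.1530	0.02706
solid_water	200	0.1363	0.02952
solid_water	300	0.1180	0.03176
solid_water	500	0.09639	0.03283
solid_water	662	0.08551	0.03274
solid_water	800	0.07826	0.03190
solid_water	1000	0.07037	0.03087
solid_water	1250	0.06291	0.02950
solid_water	1500	0.05725	0.02819
solid_water	2000	0.04917	0.02595
lung	20	0.7934	0.5393
lung	30	0.3681	0.1526
lung	40	0.2629	0.06811
lung	50	0.2224	0.04139
lung	60	0.2018	0.03126
lung	80	0.1800	0.02545
lung	100	0.1673	0.02495
lung	140	0.1507	0.02666
lung	200	0.1343	0.02908
lung	300	0.1162	0.03128
lung	500	0.09493	0.03233
lung	662	0.08422	0.03224
lung	800	0.07708	0.03142
lung	1000	0.06931	0.03041
lung	1250	0.06197	0.02906
lung	1500	0.05639	0.02776
lung	2000	0.04843	0.02556
adipose	20	0.6000	0.3960
adipose	30	0.3060	0.1108
adipose	40	0.2340	0.05080
adipose	50	0.2050	0.03260
adipose	60	0.1900	0.02620
adipose	80	0.1720	0.02310
adipose	100	0.1610	0.02340
adipose	140	0.1460	0.02560
adipose	200	0.1305	0.02820
adipose	300	0.1131	0.03040
adipose	500	0.09240	0.03150
adipose	662	0.08200	0.03140
adipose	800	0.07510	0.03060
adipose	1000	0.06750	0.02960
adipose	1250	0.06040	0.02830
adipose	1500	0.05500	0.02700
adipose	2000	0.04720	0.02490
breast	20	0.7000	0.4730
breast	30	0.3400	0.1330
breast	40	0.2510	0.06010
breast	50	0.2160	0.03740
breast	60	0.1980	0.02910
breast	80	0.1780	0.02450
breast	100	0.1660	0.02440
breast	140	0.1500	0.02640
breast	200	0.1340	0.02890
breast	300	0.1160	0.03120
breast	500	0.09460	0.03220
breast	662	0.08400	0.03210
breast	800	0.07690	0.03130
breast	1000	0.06910	0.03030
breast	1250	0.06180	0.02900
breast	1500	0.05630	0.02770
breast	2000	0.04830	0.02550
brain	20	0.8220	0.5570
brain	30	0.3790	0.1570
brain	40	0.2690	0.07000
brain	50	0.2270	0.04250
brain	60	0.2060	0.03200
brain	80	0.1840	0.02600
brain	100	0.1710	0.02550
brain	140	0.1540	0.02720
brain	200	0.1370	0.02970
brain	300	0.1190	0.03190
brain	500	0.09700	0.03300
brain	662	0.08610	0.03290
brain	800	0.07880	0.03210
brain	1000	0.07080	0.03100
brain	1250	0.06330	0.02970
brain	1500	0.05760	0.02830
brain	2000	0.04950	0.02610
liver	20	0.8280	0.5570
liver	30	0.3810	0.1570
liver	40	0.2700	0.07000
liver	50	0.2280	0.04250
liver	60	0.2060	0.03200
liver	80	0.1840	0.02600
liver	100	0.1710	0.02550
liver	140	0.1540	0.02720
liver	200	0.1370	0.02970
liver	300	0.1190	0.03190
liver	500	0.09700	0.03300
liver	662	0.08610	0.03290
liver	800	0.07880	0.03210
liver	1000	0.07080	0.03100
liver	1250	0.06330	0.02970
liver	1500	0.05760	0.02830
liver	2000	0.04950	0.02610
inner_bone	20	1.3500	1.0100
inner_bone	30	0.5880	0.2960
inner_bone	40	0.3650	0.1200
inner_bone	50	0.2770	0.06500
inner_bone	60	0.2370	0.04370
inner_bone	80	0.2000	0.03020
inner_bone	100	0.1810	0.02750
inner_bone	140	0.1600	0.02800
inner_bone	200	0.1410	0.03000
inner_bone	300	0.1210	0.03200
inner_bone	500	0.09850	0.03300
inner_bone	662	0.08730	0.03290
inner_bone	800	0.07990	0.03210
inner_bone	1000	0.07180	0.03100
inner_bone	1250	0.06420	0.02970
inner_bone	1500	0.05840	0.02840
inner_bone	2000	0.05030	0.02630
cortical_bone	20	4.0010	2.8510
cortical_bone	30	1.3310	0.9032
cortical_bone	40	0.6655	0.3910
cortical_bone	50	0.4242	0.2014
cortical_bone	60	0.3148	0.1226
cortical_bone	80	0.2229	0.05664
cortical_bone	100	0.1855	0.03786
cortical_bone	140	0.1515	0.03120
cortical_bone	200	0.1309	0.03020
cortical_bone	300	0.1113	0.03110
cortical_bone	500	0.09022	0.03160
cortical_bone	662	0.08000	0.03150
cortical_bone	800	0.07307	0.03090
cortical_bone	1000	0.06566	0.02990
cortical_bone	1250	0.05871	0.02870
cortical_bone	1500	0.05346	0.02750
cortical_bone	2000	0.04607	0.02550
titanium	20	4.9720	4.5600
titanium	30	1.5910	1.3740
titanium	40	0.7288	0.5860
titanium	50	0.4192	0.3040
titanium	60	0.2777	0.1800
titanium	80	0.1565	0.08200
titanium	100	0.1108	0.04670
titanium	140	0.0790	0.03010
titanium	200	0.0646	0.02340
titanium	300	0.0528	0.02320
titanium	500	0.0423	0.02460
titanium	662	0.0380	0.02520
titanium	800	0.0338	0.02560
titanium	1000	0.0306	0.02590
titanium	1250	0.0273	0.02520
titanium	1500	0.0249	0.02440
titanium	2000	0.0217	0.02070
cerrobend	20	55.000	30.000
cerrobend	30	20.000	12.000
cerrobend	40	9.8000	6.5000
cerrobend	50	5.6000	3.9000
cerrobend	60	3.6000	2.6000
cerrobend	80	1.8500	1.3500
cerrobend	100	1.5500	1.1000
cerrobend	140	1.0000	0.7000
cerrobend	200	0.7500	0.4500
cerrobend	300	0.4200	0.2200
cerrobend	500	0.2200	0.1000
cerrobend	662	0.1650	0.0720
cerrobend	800	0.1350	0.0580
cerrobend	1000	0.1050	0.0460
cerrobend	1250	0.0860	0.0400
cerrobend	1500	0.0740	0.0365
cerrobend	2000	0.0610	0.0340
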