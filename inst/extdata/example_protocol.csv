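"b_ms_per_um2","b_delta","theta_enc_rad","phi_enc_rad","omega_cent_hz","te_s","tr_s"
0,0,0,0,6.6,0.04,7.6
0.1,0,0,0,6.6,0.04,0.62
0.1,0,0,0,6.6,0.04,1.02347224570191
0.1,0,0,0,6.6,0.04,1.68950877051953
0.1,0,0,0,6.6,0.04,2.78897634757531
0.1,0,0,0,6.6,0.04,4.60393529945549
0.1,0,0,0,6.6,0.04,7.6
0.1,0,0,0,6.6,0.04,7.6
0.1,0,0,0,6.6,0.062,7.6
0.1,0,0,0,6.6,0.084,7.6
0.1,0,0,0,6.6,0.106,7.6
0.1,0,0,0,6.6,0.128,7.6
0.1,0,0,0,6.6,0.15,7.6
0.5,1,2.0589348976892,6.23232980114077,18.5141757879406,0.04,7.6
1,0,1.82942202776433,2.38783145563323,16.22592102997,0.06,3
1.5,-0.5,1.42456904142926,4.88483239173352,18.0370539944619,0.09,1.5
2,1,0.61561999249568,5.87292617462855,8.15438821278512,0.12,0.8
2.5,0,2.21009920507972,1.33293077275123,17.0214376229793,0.15,0.62
3,-0.5,0.648849778934245,4.09458703214518,12.5223517868668,0.04,7.6
0.5,1,0.474873566948377,0.788885934185673,18.4216266352683,0.06,3
1,0,1.2433822181706,1.67899697952353,15.9176667910069,0.09,1.5
1.5,-0.5,1.30960869291613,2.42602639316569,17.8742317769676,0.12,0.8
2,1,2.63918859321511,0.084133944562211,14.5637228876352,0.15,0.62
2.5,0,2.19944319375121,2.40261439350479,14.227961954847,0.04,7.6
3,-0.5,2.27429083408383,5.46442874361944,17.9667297363281,0.06,3
0.5,1,1.18742876772679,2.13847581530135,6.93596931360662,0.09,1.5
1,0,1.80471635674928,3.02899869841105,13.4721129365265,0.12,0.8
1.5,-0.5,1.000735996368,3.76718318499792,17.1453178368509,0.15,0.62
2,1,1.57539785886332,3.10101148893568,16.5753344133496,0.04,7.6
2.5,0,1.12049480747941,1.1700396971241,13.4777225587517,0.06,3
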