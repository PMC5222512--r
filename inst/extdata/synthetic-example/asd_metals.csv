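participant_id,group,Al,Al_censored,As,As_censored,Cd,Cd_censored,Cs,Cs_censored,Hg,Hg_censored,Ni,Ni_censored,Pb,Pb_censored,Sb,Sb_censored,Sn,Sn_censored,Tl,Tl_censored,W,W_censored
ASD-001,ASD,7.912838039073674,FALSE,11.869969927016786,FALSE,0.4992954441987973,FALSE,8.6771498720052609,FALSE,5.662995559784326,FALSE,7.072575741442825,FALSE,1.436021522497717,FALSE,0.1355269997497044,FALSE,3.2287053003044495,FALSE,0.16603114506638414,FALSE,0.7414734136708983,FALSE
ASD-002,ASD,9.381904558691023,FALSE,16.126278016644314,FALSE,0.28973020090240714,FALSE,8.838885767332362,FALSE,0.8951200661278982,FALSE,5.368864936008947,FALSE,0.5849289791294059,FALSE,0.04211325910665646,TRUE,2.683840967256859,FALSE,0.25361272599617496,FALSE,0.1471403308772447,FALSE
ASD-003,ASD,14.127164674897577,FALSE,22.73201491167181,FALSE,0.5661532567188832,FALSE,6.086870412068726,FALSE,0.9391100238288664,FALSE,5.991026505891031,FALSE,0.5393705829429238,FALSE,0.33631041081783464,FALSE,0.8308557114150316,FALSE,0.3052073353330806,FALSE,0.46809953308654917,FALSE
ASD-004,ASD,14.05642380991272,FALSE,32.94962086120101,FALSE,0.43557496921649014,FALSE,6.3616333361094695,FALSE,0.8447495750136643,FALSE,4.915461927659381,FALSE,0.8286825496961893,FALSE,0.11821117815101201,FALSE,1.6464076244510737,FALSE,0.1629506530006417,FALSE,0.1614537283006167,FALSE
ASD-005,ASD,7.204271293611024,FALSE,19.005542512113305,FALSE,0.3275102228207309,FALSE,4.880164993802427,FALSE,1.2365762708662427,FALSE,4.185366642236699,FALSE,0.18564700935027786,FALSE,0.04211325910665646,TRUE,0.94193604944772,FALSE,0.18620756487237805,FALSE,0.08753752026423865,FALSE
ASD-006,ASD,6.473770119767444,FALSE,16.577775798333285,FALSE,0.30523792545986717,FALSE,4.139036002057997,FALSE,2.2022331345210695,FALSE,4.181453182003123,FALSE,0.833307912375361,FALSE,0.21890357595788004,FALSE,1.132643663457592,FALSE,0.20328915154494534,FALSE,0.13209384836151294,FALSE
ASD-007,ASD,3.431454249444102,TRUE,6.848852105107746,FALSE,0.06192419773915741,FALSE,4.07834640149194,FALSE,0.19602239140205024,TRUE,2.568625983878611,FALSE,0.5721346679433625,FALSE,0.04211325910665646,TRUE,12.432530624285949,FALSE,0.0952506851146289,FALSE,0.12736894538331944,FALSE
ASD-008,ASD,8.945068397719615,FALSE,13.339270249249482,FALSE,0.3689374753499959,FALSE,4.806563296492474,FALSE,1.412359291417921,FALSE,4.077377551541684,FALSE,0.8803698981571887,FALSE,0.2063637739244124,FALSE,1.184227773554683,FALSE,0.14554325273385718,FALSE,0.36255219630876123,FALSE
ASD-009,ASD,6.2667250213795755,FALSE,10.186434549492056,FALSE,0.6962085111919822,FALSE,7.199905089292171,FALSE,8.985610696301428,FALSE,2.696006651840539,FALSE,0.8745477586748946,FALSE,1.2526813901553215,FALSE,2.274998945829507,FALSE,0.20340861272601088,FALSE,0.4070148214228171,FALSE
ASD-010,ASD,10.356953768783104,FALSE,14.395880627570428,FALSE,0.2688887744680081,FALSE,7.350378885598793,FALSE,1.847287054958576,FALSE,8.473528233282439,FALSE,1.4000462857474039,FALSE,0.6713421142780784,FALSE,8.886301662671634,FALSE,0.2705425411616432,FALSE,0.2181476925806159,FALSE
ASD-011,ASD,3.431454249444102,TRUE,10.864879601341066,FALSE,0.17872537661365845,FALSE,1.7593488230654646,FALSE,0.3593200653548302,FALSE,5.659729592029193,FALSE,0.22374886088098703,FALSE,0.24846883286013557,FALSE,1.5648927253320961,FALSE,0.13012066910938708,FALSE,0.23767284234892627,FALSE
ASD-012,ASD,10.391790888303342,FALSE,14.06878426983403,FALSE,0.49442108262461687,FALSE,3.011240118111257,FALSE,2.547616227440164,FALSE,5.868237680783385,FALSE,0.7881040774816316,FALSE,0.04211325910665646,TRUE,1.519065659488008,FALSE,0.22103397211638326,FALSE,0.24723268014188113,FALSE
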