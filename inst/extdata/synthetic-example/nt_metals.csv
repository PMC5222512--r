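participant_id,group,Al,Al_censored,As,As_censored,Cd,Cd_censored,Cs,Cs_censored,Hg,Hg_censored,Ni,Ni_censored,Pb,Pb_censored,Sb,Sb_censored,Sn,Sn_censored,Tl,Tl_censored,W,W_censored
NT-001,NT,6.884847587340115,FALSE,21.20866831829375,FALSE,0.6752454305686152,FALSE,6.5188392241273965,FALSE,0.5109529365955391,FALSE,4.660651548369491,FALSE,0.3196734616443179,FALSE,0.6989493614992248,FALSE,2.213196372736699,FALSE,0.14565181075084246,FALSE,1.0228573621578863,FALSE
NT-002,NT,3.431454249444102,TRUE,10.144229126933485,FALSE,0.26948427364742145,FALSE,2.726391724082458,FALSE,5.421306221654969,FALSE,3.8464262205545188,FALSE,0.3010582506443959,FALSE,0.04211325910665646,TRUE,0.48306236742727304,FALSE,0.14010757040208324,FALSE,0.1582374496013428,FALSE
NT-003,NT,6.760779573480479,FALSE,9.614105982844912,FALSE,0.33308481497738746,FALSE,4.228580695779559,FALSE,0.5112814293063082,FALSE,2.889916731567037,FALSE,0.2040771055478393,FALSE,0.04211325910665646,TRUE,1.03364171547582,FALSE,0.12808376577999311,FALSE,0.13542350809253767,FALSE
NT-004,NT,7.772318265804279,FALSE,10.668955969136471,FALSE,0.35583778804411575,FALSE,3.4291243959760838,FALSE,4.744822628255021,FALSE,6.055422994001107,FALSE,0.68918354004543,FALSE,0.1357723699087282,FALSE,2.239425490617103,FALSE,0.14908467921951218,FALSE,0.3920827703411612,FALSE
NT-005,NT,3.431454249444102,TRUE,8.80030757291139,FALSE,0.23451431830255015,FALSE,2.44828646949908,FALSE,0.4105174017432918,FALSE,1.722847994398525,FALSE,0.21909323645476644,FALSE,0.04211325910665646,TRUE,0.12866108500384738,TRUE,0.07253867401865087,FALSE,0.2563485947168483,FALSE
NT-006,NT,3.431454249444102,TRUE,8.538909806707405,FALSE,0.17443315850581464,FALSE,2.4990583205863177,FALSE,0.19602239140205024,TRUE,3.549605057606048,FALSE,0.16064057571084334,FALSE,0.04211325910665646,TRUE,0.6145313919004889,FALSE,0.06899531613224588,FALSE,0.21902315355313481,FALSE
NT-007,NT,3.431454249444102,TRUE,8.553827859819167,FALSE,0.1363030994482835,FALSE,2.328974012252292,FALSE,0.19602239140205024,TRUE,2.553960218314799,FALSE,0.2398563215912873,FALSE,0.20274470767633732,FALSE,0.8349042113198583,FALSE,0.10085593396202924,FALSE,0.22362220861857549,FALSE
NT-008,NT,6.689062227959187,FALSE,5.568160688658903,FALSE,0.27075356178645754,FALSE,7.69343938371965,FALSE,0.19602239140205024,TRUE,3.570450917642611,FALSE,0.26187076668054676,FALSE,0.04211325910665646,TRUE,0.5642584483986941,FALSE,0.13949847659003592,FALSE,0.12389400495166779,FALSE
NT-009,NT,6.090185572060393,FALSE,15.71241045351736,FALSE,0.4682270569750917,FALSE,2.5824476556711864,FALSE,2.380757508828352,FALSE,4.2008988885935885,FALSE,0.32805933828144723,FALSE,0.7398032164777943,FALSE,1.3486636466224766,FALSE,0.14763321300286858,FALSE,0.5170530953280946,FALSE
NT-010,NT,5.36126959834825,FALSE,4.271736029764841,FALSE,0.3949783164691754,FALSE,2.172248179486017,FALSE,0.19602239140205024,TRUE,2.0471116932074933,FALSE,0.4859721655476724,FALSE,0.04211325910665646,TRUE,0.9358240996938353,FALSE,0.12832862840465042,FALSE,0.24006306265836844,FALSE
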