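time,X_obs:1,X_obs:2,X_obs:3,X_obs:4,X_obs:5,X_obs:6,Y_obs:1,Y_obs:2,Y_obs:3,Y_obs:4,Y_obs:5,Y_obs:6
0,0,0,0,0,0,0,0,0,0,0,0,0
1,0.0165397787595809,0.0185541401894008,0.0154413415654415,0.0169303305130345,0.0172135361064645,0.0168581406027817,0.00448671074611898,0.00450797768633556,0.0035695998959963,0.00361515147152207,0.0039106295734879,0.00409387436739594
2,0.0145158512022629,0.0151869550471801,0.0169183741885716,0.0143285851180511,0.0140243896330108,0.0134523657603574,0.00897765084766264,0.00841016601912361,0.00905004139669464,0.00963212898214328,0.0102990955780127,0.00767346248875207
4,0.00817130919151842,0.00861438772438316,0.007689715690213,0.00969405572071941,0.00814449617272287,0.0100660288691018,0.0129298186204747,0.0130817316093745,0.0125438666762044,0.0110169565708627,0.0125343459280418,0.0118469591912835
8,0.00688120357387938,0.00801975025736281,0.00717112702999767,0.00792302476007461,0.00692276905582401,0.00655807263100613,0.0120368287670416,0.0120914716931967,0.0121114099780366,0.0134735354117379,0.0133274856816931,0.0113556437296056
12,0.00733196406959997,0.00677804845225151,0.00772081698351545,0.00721256054419135,0.00523921826335814,0.00772735954318285,0.0129680156202534,0.0116756450726863,0.0113419702273498,0.0118141496092101,0.0127103273063339,0.0119807007775453
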