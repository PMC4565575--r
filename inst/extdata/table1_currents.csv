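metastasis,pair,voltage_V,i_meas_A,i_comp_A
1,1-2,1200,21.5,22.6
1,1-4,1200,20.7,20.4
1,2-3,1200,17.6,19.5
1,3-4,1200,20.9,21.2
1,2-5,1000,17.8,21.1
1,1-5,1000,23.5,22
1,3-5,1000,17.8,20.2
1,4-5,1000,16.2,19.5
2,1-2,1200,22.2,18.4
2,1-4,1200,17.6,15.5
2,2-3,1200,20.2,17.5
2,3-4,1200,17.6,22.2
2,2-5,1000,17.8,17.1
2,1-5,1000,17.2,20
2,3-5,1000,16.1,15.6
2,4-5,1000,12.6,19.9
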