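(((out1:0.4,out2:0.4):0.5,(out3:0.4,out4:0.4):0.5):2.1,(((nsA1:1,(nsA2:0.75,(nsA3:0.5,(nsA4:0.25,nsA5:0.25):0.25):0.25):0.25):1,((sacE1:0.3,sacE2:0.3):0.4,(sacE3:0.3,sacE4:0.3):0.4):1.3):0.5,((((nsB1:0.3,nsB2:0.3):0.4,(nsB3:0.3,nsB4:0.3):0.4):1,(sacF1:0.3,sacF2:0.3):1.4):0.5,(((nsC1:0.6,(nsC2:0.3,nsC3:0.3):0.3):0.8,(sacG1:0.3,sacG2:0.3):1.1):0.5,(((hgrandis_like:0.3,hnsp3_like:0.3):0.5,(hmac_like:0.3,hnsp2_like:0.3):0.5):0.4,relictum_like:1.2):0.7):0.3):0.3):0.5);
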