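sex,band,yll,yll_lo,yll_hi,yld,yld_lo,yld_hi,daly,daly_lo,daly_hi
male,0-5,0,0,0,0.5,0.2,0.8,0.5,0.2,0.8
male,6-12,9.2,0,18.5,1.0,0.6,1.5,10.2,0.8,23.9
male,13-18,0,0,0,1.1,0.7,1.5,1.1,0.7,1.5
male,19-28,0,0,0,0.8,0.5,1.0,0.8,0.5,1.0
male,29-49,4.4,0,9.2,1.8,1.4,2.2,6.2,1.6,12.6
male,50+,14.8,3.8,27.1,1.7,1.0,2.3,16.5,5.2,28.9
male,all,3.9,1.7,6.2,1.1,1.0,1.3,5.0,2.8,7.4
female,0-5,0,0,0,0.1,0,0.3,0.1,0,0.3
female,6-12,0,0,0,0.5,0.3,0.8,0.5,0.3,0.8
female,13-18,0,0,0,0.8,0.5,1.1,0.8,0.5,1.1
female,19-28,5.5,0,11.6,1.1,0.8,1.5,6.6,1.0,14.7
female,29-49,2.3,0,6.8,1.5,1.2,1.9,3.8,1.2,8.4
female,50+,4.5,0,9.5,1.2,0.8,1.6,5.7,1.0,12.3
female,all,2.3,0.6,4.0,1.0,0.8,1.1,3.2,1.5,5.0
both,0-5,0,0,0,0.3,0.2,0.5,0.3,0.2,0.5
both,6-12,4.5,0,9.2,0.8,0.6,1.0,5.3,0.7,11.9
both,13-18,0,0,0,1.0,0.7,1.2,1.0,0.7,1.2
both,19-28,2.7,0,6.8,0.9,0.7,1.2,3.7,0.9,6.8
both,29-49,3.3,1.0,6.8,1.6,1.4,1.9,4.9,1.9,8.4
both,50+,8.5,3.0,15.1,1.4,1.1,1.8,9.9,4.1,16.0
both,all,3.0,1.6,4.5,1.0,0.9,1.1,4.1,2.7,5.7
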