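subject,si,hd_median_mm,hd_q1_mm,hd_q3_mm,days_between_scans
A1,0.88,6.6,5.7,8.4,20
A2,0.93,3.2,2.8,3.8,1
A3,0.91,4.5,4.5,4.8,11
A4,0.91,4.1,3.6,4.8,6
A5,0.93,3.0,2.2,4.0,2
A6,0.91,5.2,4.4,6.8,6
A7,0.90,7.3,6.7,8.2,2
A8,0.91,5.1,4.5,6.0,31
A9,0.90,4.7,3.8,5.6,27
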