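admin_id,patient_id,activity_MBq,flow_l_min,instrument,timepoint,reading_1,reading_2,outlier_2,decay_factor,conv_factor,final_printed,per_unit_printed
A01,NA,4.37,4,PQ2000,early,> 4.61,> 4.61,FALSE,1.054,2.3,> 4.61,> 1.05
A01,NA,4.37,4,PQ2000,late,> 4.82,> 4.82,FALSE,1.054,2.3,> 4.82,> 1.10
A02,NA,4.36,4,PQ2000,early,4.61,4.61,FALSE,1.054,2.3,4.61,1.06
A02,NA,4.36,4,PQ2000,late,4.61,4.82,FALSE,1.054,2.3,4.82,1.11
A03,NA,4.87,4,PQ2000,early,4.82,4.82,FALSE,1.054,2.3,4.82,0.99
A03,NA,4.87,4,PQ2000,late,4.82,4.82,FALSE,1.054,2.3,4.82,0.99
A04,NA,3.10,4,PQ2000,early,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 1.57
A04,NA,3.10,4,PQ2000,late,3.87,< 1.45,TRUE,1.054,2.3,3.87,1.25
A05,NA,5.06,4,PQ2000,early,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 0.96
A05,NA,5.06,4,PQ2000,late,> 4.85,4.29,FALSE,1.054,2.3,> 4.29,> 0.85
A06,NA,3.33,1,PQ2000,early,5.37,5.37,FALSE,1.234,2.3,5.37,1.61
A06,NA,3.33,1,PQ2000,late,1.96,2.12,FALSE,1.234,2.3,2.04,0.61
A07,NA,3.99,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.42
A07,NA,3.99,1,PQ2000,late,4.63,4.43,FALSE,1.234,2.3,4.53,1.13
A08,NA,3.75,4,PQ2000,early,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 1.29
A08,NA,3.75,4,PQ2000,late,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 1.29
A09,NA,4.62,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.23
A09,NA,4.62,1,PQ2000,late,5.53,> 5.68,FALSE,1.234,2.3,> 5.53,> 1.20
A10,NA,4.43,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.28
A10,NA,4.43,1,PQ2000,late,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.28
A11,NA,5.49,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.03
A11,NA,5.49,1,PQ2000,late,4.42,3.66,FALSE,1.234,2.3,4.04,0.74
A12,NA,5.12,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.11
A12,NA,5.12,1,PQ2000,late,< 1.70,< 1.70,FALSE,1.234,2.3,< 1.70,< 0.33
A13,NA,4.89,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.16
A13,NA,4.89,1,PQ2000,late,3.28,3.04,FALSE,1.234,2.3,3.16,0.65
A14,NA,5.20,1,PQ2000,early,> 5.68,> 5.68,FALSE,1.234,2.3,> 5.68,> 1.09
A14,NA,5.20,1,PQ2000,late,3.32,2.98,FALSE,1.234,2.3,3.15,0.61
A15,NA,3.77,4,PQ2000,early,4.85,4.18,FALSE,1.054,2.3,4.51,1.20
A15,NA,3.77,4,PQ2000,late,3.30,3.30,FALSE,1.054,2.3,3.30,0.87
A16,NA,3.74,4,PQ2000,early,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 1.30
A16,NA,3.74,4,PQ2000,late,> 4.85,> 4.85,FALSE,1.054,2.3,> 4.85,> 1.30
A17,NA,4.33,4,PQ2000,early,-,-,FALSE,1.054,2.3,-,-
A17,NA,4.33,4,PQ2000,late,2.58,2.39,FALSE,1.054,2.3,2.48,0.57
A18,NA,NA,NA,P30F,early,-,-,FALSE,NA,NA,-,-
A19,NA,NA,NA,P30F,early,-,-,FALSE,NA,NA,-,-
A20,NA,NA,NA,P30F,early,-,-,FALSE,NA,NA,-,-
A21,NA,NA,NA,P30F,early,-,-,FALSE,NA,NA,-,-
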