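characteristic,category,count
age_group,<=40,134
age_group,41-50,247
age_group,>50,320
treatment,FAC,74
treatment,FAC+paclitaxel,236
treatment,FAC+docetaxel,61
treatment,FEC,33
treatment,FEC+paclitaxel,73
treatment,paclitaxel,65
treatment,docetaxel,39
treatment,unspecified,120
response,pCR or RCB 0-1,188
response,no pCR or RCB 2-3,492
response,unspecified,21
er_status,positive,385
er_status,negative,300
er_status,unspecified,16
her2_status,positive,65
her2_status,negative,561
her2_status,unspecified,75
subtype,Basal,211
subtype,LumA,216
subtype,LumB,135
subtype,HER2-E,74
subtype,Claudin-low,47
subtype,Normal-like,16
subtype,unspecified,2
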