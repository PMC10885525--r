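algorithm_id,label,N,n
1a,>= 1 day with an HIV diagnosis code,272,219
1b,>= 2 days with an HIV diagnosis code,230,216
1c,>= 3 days with an HIV diagnosis code,219,213
2a,>= 1 HIV code day during 1/1/2010-9/30/2015 (ICD-9-CM era),139,108
2b,>= 1 HIV code day during 1/1/2010-12/31/2012 (earlier ICD-9-CM era),106,83
2c,>= 1 HIV code day during 1/1/2013-9/30/2015 (later ICD-9-CM era),33,25
3a,>= 1 HIV code day during 10/1/2015-12/31/2020 (ICD-10-CM era),133,110
3b,>= 1 HIV code day during 10/1/2015-12/31/2017 (earlier ICD-10-CM era),38,27
3c,>= 1 HIV code day during 1/1/2018-12/31/2020 (later ICD-10-CM era),95,83
4a,>= 1 day with ICD-9-CM 042 (HIV disease),110,91
4b,>= 1 day with ICD-9-CM V08 (asymptomatic HIV infection status),98,82
4c,>= 1 day with ICD-9-CM 079.53 (HIV type 2),2,2
4d,>= 1 day with ICD-9-CM 795.71 (nonspecific serologic evidence of HIV),5,2
5a,>= 1 day with ICD-10-CM B20 (HIV disease),119,104
5b,>= 1 day with ICD-10-CM Z21 (asymptomatic HIV infection status),100,92
5c,>= 1 day with ICD-10-CM B97.35 (HIV type 2),0,0
5d,>= 1 day with ICD-10-CM O98.711-O98.73 (HIV in pregnancy/childbirth/puerperium),10,10
6a,>= 1 HIV code day & >= 1 CD4 procedure day on/after first HIV code,218,205
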