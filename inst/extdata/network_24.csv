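id,name,length_cm,r_top_cm,r_bottom_cm,daughter_1,daughter_2,bed_root_radius_cm
1,ascending_aorta,7.0,1.25,1.14,2,3,
2,brachiocephalic,3.5,0.70,0.70,4,5,
3,aortic_arch_1,1.8,1.14,1.11,6,7,
4,r_subclavian_brachial,43.0,0.44,0.28,,,0.28
5,r_common_carotid,17.0,0.29,0.28,,,0.28
6,l_common_carotid,19.0,0.29,0.28,,,0.28
7,aortic_arch_2,1.0,1.11,1.09,8,9,
8,l_subclavian_brachial,43.0,0.42,0.28,,,0.28
9,thoracic_aorta,18.8,1.09,0.85,10,11,
10,celiac,3.0,0.33,0.30,,,0.30
11,abdominal_aorta_1,2.0,0.85,0.83,12,13,
12,superior_mesenteric,5.0,0.435,0.435,,,0.435
13,abdominal_aorta_2,2.0,0.83,0.80,14,15,
14,r_renal,3.0,0.28,0.275,,,0.275
15,abdominal_aorta_3,1.0,0.80,0.79,16,17,
16,l_renal,3.0,0.28,0.275,,,0.275
17,abdominal_aorta_4,6.0,0.79,0.73,18,,
18,abdominal_aorta_5,3.0,0.73,0.70,19,20,
19,r_external_iliac,6.5,0.45,0.43,21,22,
20,l_external_iliac,6.5,0.45,0.43,23,24,
21,r_femoral,13.0,0.43,0.40,,,0.40
22,r_internal_iliac,4.5,0.20,0.20,,,0.20
23,l_femoral,13.0,0.43,0.40,,,0.40
24,l_internal_iliac,4.5,0.20,0.20,,,0.20
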