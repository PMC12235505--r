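assignment,type,n_range,m_range,gcms_ions,di_detected,hplc_ions,confirmed,concentration_ug_g,concentration_sd,surrogate_rf,representative_species
ATBC,Plasticiser,,,185;129;259,no,129.01831;185.08102;139.00272,yes,4210,135,no,
TBA,NIAS,,,113;157;57,no,139.00261;157.01319;111.00773,,1400,170,yes,
TBC,Plasticiser,,,185;129;57,no,,,104,23,yes,
Palmitic acid,Lubricant,,,117;313;129,no,,yes,18,3,yes,
Stearic acid,Lubricant,,,117;129;132,no,,yes,4,2,yes,
PMP,Unknown,,,191;244;73,yes,357.29994;71.04916;101.05974,,,,,
PMP-LA,Unknown,,,191;244;147,yes,429.32104;83.04915;95.08555,,,,,
PMP-[LA]n,Unknown,2-4,,,yes,,,,,,
PMS,Unknown,,,117;191;73,yes,385.33136;71.04916;83.04916,yes,,,,
PMS-LA,Unknown,,,117;191;73,yes,457.35227;83.04912;95.08551,,,,,
PMS-[LA]n,Unknown,2-6,,,yes,,,,,,
[AA-BD],Cyclic/NIAS,,,55;129;111,yes,,yes,168,32,no,cyclic [AA-BD]
[AA-BD]2,Cyclic/NIAS,,,129;111;201,yes,201.11221;111.04412;401.21721,yes,772,5,no,cyclic [AA-BD]2
[AA-BD]n,Cyclic/NIAS,3-5,,,yes,201.11221;111.04412;401.21721,,,,,cyclic [AA-BD]5
[AA-BD]6,Cyclic/NIAS,,,,yes,,,,,,cyclic [AA-BD]6
[AA-BD]-[TA-BD],Cyclic/NIAS,,,149;104;221,yes,221.08086;149.02332;111.04408,,480,12,yes,cyclic [AA-BD]-[TA-BD]
[AA-BD]m-[TA-BD]n,Cyclic/NIAS,2-3,1,,yes,387.10743;221.08101;149.02334,,,,,cyclic [AA-BD]-[TA-BD]3
[AA-BD]m-[TA-BD]n,Cyclic/NIAS,1-3,2-4,,yes,221.08084;421.18570;149.02333,,,,,cyclic [AA-BD]4-[TA-BD]3
[AA-BD]m-[TA-BD]n,Cyclic/NIAS,1-4,5,,n=1-3,221.08083;387.10739;421.18582,,,,,cyclic [AA-BD]5-[TA-BD]4
[AA-BD]m-[TA-BD]n,Cyclic/NIAS,1-3,6,,n=1,201.11219;221.08089;401.21704,,,,,cyclic [AA-BD]6-[TA-BD]3
[AA-BD]m-[TA-BD]n,Cyclic/NIAS,1,7,,,201.11222;221.08093;401.21714,,,,,cyclic [AA-BD]7-[TA-BD]
[AA-BD]n-[TA-BD],Linear/NIAS,2-4,,,yes,,,,,,linear [AA-BD]4-[TA-BD]
BD-[AA-BD]n,Linear/NIAS,2-4,,,yes,,,,,,BD-[AA-BD]4
BD-[AA-BD]m-[TA-BD]n,Linear/NIAS,1;2,1,,yes,,,,,,BD-[AA-BD]-[TA-BD]2
BD-[AA-BD]m-[TA-BD]n,Linear/NIAS,2;3,2,,yes,,,,,,BD-[AA-BD]2-[TA-BD]3
BD-[AA-BD]m-[TA-BD]n,Linear/NIAS,1;3,3,,yes,,,,,,BD-[AA-BD]3-[TA-BD]3
BD-[AA-BD]m-[TA-BD]n,Linear/NIAS,1-2,4,,yes,,,,,,BD-[AA-BD]4-[TA-BD]2
Me-[LA]7-[AA-BD]n,Linear/NIAS,0-2;4,,,yes,,,,,,Me-[LA]7-[AA-BD]4
[TA-BD]2,Cyclic/NIAS,,,132;149;104,yes,387.10762;149.02344;369.09713,yes,348,9,no,cyclic [TA-BD]2
[TA-BD]3,Cyclic/NIAS,,,,yes,149.02336;387.10745;589.17051,yes,,,,cyclic [TA-BD]3
[TA-BD]-[SeA-BD],Cyclic/NIAS,,,149;221;166,yes,149.02332;405.19086;221.08094,,297,7,yes,cyclic [TA-BD]-[SeA-BD]
[TA-BD]m-[SeA-BD]n,Cyclic/NIAS,2-5,1,,n=2-4,149.02336;203.12774;257.17491,,,,,cyclic [TA-BD]-[SeA-BD]5
[TA-BD]m-[SeA-BD]n,Cyclic/NIAS,1-4,2,,yes,149.02336;203.12774;387.10728,,,,,cyclic [TA-BD]2-[SeA-BD]4
[TA-BD]m-[SeA-BD]n,Cyclic/NIAS,1-4,3,,n=1-3,149.02336;387.10728;203.12774,,,,,cyclic [TA-BD]3-[SeA-BD]4
[SeA-BD],Cyclic/NIAS,,,166;98;138,yes,185.11730;257.17473;203.12781,,588,15,yes,cyclic [SeA-BD]
[SeA-BD]2,Cyclic/NIAS,,,185;257;166,yes,185.11730;257.17491;513.34218,,252,3,yes,cyclic [SeA-BD]2
[SeA-BD]n,Cyclic/NIAS,3-4,,,yes,257.17487;203.12789;185.11733,,,,,cyclic [SeA-BD]4
[LA]2,Cyclic/NIAS,,,56;28;43,,,yes,,,,cyclic [LA]2
[LA]n,Cyclic/NIAS,6-12,,,yes,,,,,,cyclic [LA]12
[LA]n-Me,Linear/NIAS,2,,,yes,,,,,,Me-[LA]2
[LA]n-Me,Linear/NIAS,3-10,,,yes,105.05464;145.04955;89.05973,,,,,Me-[LA]10
[LA]n-Me,Linear/NIAS,11-20,,,yes,,,,,,Me-[LA]20
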