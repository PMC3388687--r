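patient_id,age,apache2,sofa,days_hosp_to_icu,bmi,n_comorbid,il6,crp,pct,oral_intake_pct,weight_loss_pct,mort28,mv_start_within_48h,mv_days,icu_days,energy_prescribed,energy_received_daily
P00001,43.5280504118581,18,6,0.0402426087530330,25.2959093927484,1,171.50010818679607,131.2079526401141,25.8534919825833924,6,1.3,0,0,0,1.213404497916727,2069,1355;860
P00002,69.2882568430820,24,10,0.4332739634699998,28.2180753848640,4,215.55487785756591,48.0023097307598,0.1007054164286225,100,0.0,0,1,4,5.143399616238983,2032,1850;1546;1605;1664;1726;632
P00003,84.6107970360975,18,5,0.5754476745936932,26.8838941666971,2,12.31425939319152,132.0929894891615,0.4801472840443910,,,1,0,0,7.744340467000772,2363,1471;1323;1523;1242;1488;1292;1271;617
P00004,88.4810294981288,30,6,0.0199296473758295,28.3955474404774,0,3.11568828831272,71.8261644664786,3.0944075777056379,,,1,1,6,7.909770853387054,1797,11;11;13;14;14;11;14;4
P00005,46.6167378900813,15,11,1.0199926116128764,26.5479905419708,4,406.12542737145930,114.9282163201993,0.7019487687242132,,,1,0,0,2.311109535505213,1656,317;315;257
P00006,58.6879085132436,13,10,2.3350980376729065,26.2412500812144,1,4252.82886337153741,32.0608688064283,2.6556530519131551,,,1,0,0,1.058365956932644,2196,503;117
P00007,87.0464028191746,25,12,0.3492709844526647,18.0867226797815,4,1770.14999153451254,328.1324009579085,30.0904222373996930,13,3.6,0,0,0,1.648611542782144,1486,473;219
P00008,74.4352306055759,24,4,3.2111662771995571,23.8195431154634,1,9.17765279836371,144.4669879121883,5.7341345364628751,,,0,0,0,1.591136884966690,2367,2315;952
P00009,83.4995321523893,24,5,0.0428004173329100,,0,27.87723063783579,73.4132588079447,1.1959148454975521,,,0,0,0,2.511999142310459,1998,1548;1574;798
P00010,75.5690874757851,32,5,1.0035830579312186,36.3517138111603,4,1681.00724234182644,16.8913196334980,5.9801709947180042,100,0.0,0,1,10,10.874937712753406,2238,1799;1760;1740;2271;1952;1801;1763;2262;2082;1976;877
P00011,86.6201257045274,8,7,0.0625582113396376,24.9272161387177,2,141.12348253511945,30.2695152117562,0.4865084886825994,100,0.0,0,1,5,5.687108651283005,1987,1173;1197;1534;1287;1507;642
P00012,52.9086850774598,25,4,1.8917219918056847,28.3064715736433,0,45.02135051129777,107.8536199849920,24.8229881937450649,,,1,0,0,1.906701070689278,2422,1299;454
P00013,65.1379042342168,30,11,0.0544640868669376,28.6459778987082,0,100.16031664875271,81.0245555092912,0.0569814261112354,,,0,1,3,5.916820666144848,1784,1355;1234;1473;1224;1285;705
P00014,40.0826890164402,24,13,0.0379012763267383,22.8164652360236,0,400.03352192899729,144.3224662525209,10.2467302457054856,,,0,1,1,1.891369951510894,2102,562;214
P00015,62.5307146028832,34,5,0.0446275207912549,26.2493598616499,2,10.45712113845830,491.0321346019546,1.3040433606546755,,,0,0,0,0.948626052280412,2327,790
P00016,96.6349654004101,18,4,70.6968820514087781,,4,34.78485467415069,215.7849573762566,0.7468353185321408,,,0,1,22,28.000000000000000,1660,1279;1297;1343;1533;1500;1276;1357;1466;1444;1268;1407;1459;1260;1453
P00017,58.5043683012088,17,4,0.0312779421918094,32.9863868310238,4,73.27654312146208,501.1801151956158,0.4407254677331955,,,0,0,0,0.735948119124197,1864,285
P00018,55.1106353877151,16,8,0.3520320657651976,49.6281737072581,4,81.08251867980469,78.5380235245934,79.7613364910491782,11,0.0,1,0,0,2.397545995560397,2247,1040;1046;399
P00019,48.2639720354706,18,6,0.1194411432837234,25.8022856697400,1,243.77311007797397,82.1040430558501,0.0245672321581898,,,0,1,5,6.246184475346505,1200,1007;1112;1177;933;902;1007;232
P00020,40.3082412775861,24,7,3.4647472576472405,29.5193660217097,3,35.08281551934116,180.5533238105771,2.0346188013005277,71,0.0,0,0,0,2.923624262861208,1808,1025;1094;257
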