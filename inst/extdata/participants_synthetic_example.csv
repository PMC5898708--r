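"id","trt","dur_mhl","dur_shl","hearing_aid_use","b1","b2","ap","srt"
"p001",61.33862602432,20.3183049056679,1.07471990049817,"none",3.77564808260649,2.97365278331563,1.18407322020503,3.96592702226775
"p002",43.9177164574352,5.13792991172522,3.51197735290043,"none",2.43913167528808,0.140331996139139,-1.51720141117694,3.71038133322655
"p003",52.2681557020361,7.83263891469687,5.40963537641801,"both_sides",2.39947543432936,0.463810754939914,-1.37255668049911,0.762704217868464
"p004",54.6957634446494,15.4323880397715,11.9849641050678,"both_sides",1.21456773998216,1.44085539365187,-6.28725996279391,2.80290106443784
"p005",52.638414908269,20.2682182355784,4.93525855708867,"none",-1.98636220348999,1.53806982142851,-9.20624717862811,0.431216242525445
"p006",48.0448793551766,29.4845159375109,17.9838959418703,"none",1.65362471528351,2.31794375414029,-17.736503827956,4.15060363861361
"p007",62.6036979769504,22.7863280265592,0.1971184683498,"one_side",3.02080935658887,0.369838271290064,-1.97636363797355,2.89692145987116
"p008",48.1480686542821,16.9946527224965,9.38724911538884,"none",2.50913537619635,3.51522357482463,-5.67582794092596,5.37871918701191
"p009",67.1658134248934,25.4906915570609,12.8601927077398,"one_side",0.716389435343444,3.77542176144198,-9.60157119429205,-0.477213606674325
"p010",48.4355731085282,5.68421806208789,0.0392638554330915,"one_side",1.21473996294662,-0.598858846817166,-0.716617905627936,2.27198778515998
"p011",60.7438268880114,8.13859844114631,14.5401000627317,"one_side",1.22426017187536,2.34698559995741,-7.60629590977915,1.32397331705124
"p012",69.57980853431,24.8447545571253,3.94763020449318,"none",-1.99171493854374,3.42180715082213,-7.56073440558976,1.97927238790824
"p013",36.5002536899889,20.7961446116678,8.97570764645934,"one_side",0.133995722979307,1.62084450852126,-8.77272592291702,1.30837118713513
"p014",46.4909010986437,7.21634218934923,16.1407969600987,"none",1.67279854090884,1.78904379345477,-11.5947778460686,3.85314681706964
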