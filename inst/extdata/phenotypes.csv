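sample_id,age,sex,bmi,huc1,huc2,huc3,huc4,huc5,huc6,huc7,huc8,huc9,huc10,huc11,huc12,huc13,huc14
S0001,27.196980246576,male,23.5231932288918,3,3,3,2,2,2,2,2,2,2,2,2,2,2
S0002,44.2338131751209,male,21.9563252315886,1,1,1,1,1,1,1,1,0,0,0,0,0,0
S0003,41.5203260646665,male,23.2269731681945,3,3,3,3,3,3,3,3,3,3,3,2,2,2
S0004,41.4609835795239,male,22.095692826645,2,2,2,2,2,2,2,2,1,1,1,1,1,1
S0005,47.1645800255371,male,20.8039656490201,3,3,3,3,3,3,2,2,2,2,2,2,2,2
S0006,44.039389171185,male,22.0244403142754,1,1,1,1,1,1,1,1,1,1,1,0,0,0
S0007,39.591730901953,male,21.6181878325579,1,1,1,0,0,0,0,0,0,0,0,0,0,0
S0008,39.8209893486315,male,21.9349448974485,4,4,4,4,4,4,4,4,4,4,4,3,3,3
S0009,49.8242267970746,male,20.8629257590018,2,2,2,2,2,2,2,2,2,2,2,1,1,1
S0010,46.75821128514,male,21.0949655423207,4,4,4,4,4,4,4,4,4,4,4,3,3,3
S0011,46.6656227630943,male,27.2637596449813,4,4,4,4,4,4,4,3,3,3,3,3,3,3
S0012,56.8740350680082,male,24.5850614944436,3,3,3,3,3,3,2,2,2,2,2,2,2,2
S0013,44.4692422304192,male,25.0091780619588,2,2,2,2,2,2,2,2,2,2,2,2,2,1
S0014,40.7863545800656,male,20.3591325922081,3,3,3,3,3,3,3,3,2,2,2,2,2,2
S0015,44.1353570764238,male,18.933183742632,1,1,1,1,1,1,1,1,1,1,0,0,0,0
S0016,40.3655784117214,male,27.4595737891686,3,3,3,3,3,3,3,3,3,3,3,3,3,3
S0017,37.1765167149564,male,22.7241312729411,3,3,3,3,2,2,2,2,2,2,2,2,2,2
S0018,40.0211741666875,female,15.4458178201115,2,2,2,2,2,2,2,2,2,2,1,1,1,1
S0019,47.6422738199615,male,26.8854998541033,1,0,0,0,0,0,0,0,0,0,0,0,0,0
S0020,32.1356875132187,male,27.6463361880935,2,2,2,2,2,2,2,2,2,2,2,1,1,1
S0021,44.2544211551754,female,22.5534683412531,2,2,2,1,1,1,1,1,1,1,1,1,1,1
S0022,38.9501722158502,male,25.5032566444446,4,3,3,3,3,3,3,3,3,3,3,3,3,3
S0023,33.0269323578341,female,19.1089266873884,3,3,3,3,3,3,3,3,3,3,3,3,3,2
S0024,30.067156374681,male,26.8270520383224,1,1,1,1,1,1,1,1,1,1,0,0,0,0
S0025,37.3081443022756,male,26.084790614539,3,3,3,2,2,2,2,2,2,2,2,2,2,2
S0026,30.9530699957362,female,22.924351352977,3,3,3,3,2,2,2,2,2,2,2,2,2,2
S0027,42.5166953359851,female,20.2743631832454,2,1,1,1,1,1,1,1,1,1,1,1,1,1
S0028,41.876923815276,male,18.6442716600409,1,1,1,1,1,0,0,0,0,0,0,0,0,0
S0029,37.4751367810275,male,15.433098488674,2,2,2,2,2,2,2,2,2,2,2,1,1,1
S0030,37.7771425110176,female,24.3586121445725,3,2,2,2,2,2,2,2,2,2,2,2,2,2
S0031,48.9006436760187,male,20.6351195354337,2,2,2,2,2,2,2,1,1,1,1,1,1,1
S0032,48.4406995929292,male,20.8607986255475,3,3,3,2,2,2,2,2,2,2,2,2,2,2
S0033,47.6347021857887,male,18.0586851926351,3,3,3,3,3,3,3,3,3,3,2,2,2,2
S0034,56.9529550857191,male,24.456817346648,3,3,3,3,3,3,2,2,2,2,2,2,2,2
S0035,50.0009791558204,male,20.9638744213917,3,3,3,3,3,3,3,3,3,3,3,3,3,3
S0036,40.9901463690781,male,21.9575958856658,3,3,3,3,3,2,2,2,2,2,2,2,2,2
S0037,45.364956651659,male,20.269803961597,2,2,2,2,2,2,2,2,2,2,2,1,1,1
S0038,37.0196834405184,female,21.0299932647138,3,3,3,2,2,2,2,2,2,2,2,2,2,2
S0039,43.2476166688592,male,19.2882688010682,2,1,1,1,1,1,1,1,1,1,1,1,1,1
S0040,35.9452595840175,female,19.4932634758043,3,3,3,3,3,3,2,2,2,2,2,2,2,2
S0041,39.5495288945434,male,21.6137177622357,1,1,1,1,1,1,1,1,0,0,0,0,0,0
S0042,44.7903069207465,male,17.197334378449,2,2,2,2,2,2,2,2,2,2,2,2,2,1
S0043,42.1790333775208,female,19.8852003824889,3,3,3,2,2,2,2,2,2,2,2,2,2,2
S0044,46.7323276752088,female,21.738171448465,1,0,0,0,0,0,0,0,0,0,0,0,0,0
S0045,31.2854523504597,male,25.0406132887585,2,2,2,2,1,1,1,1,1,1,1,1,1,1
S0046,29.8596784474455,male,20.1965687709684,3,3,3,3,3,3,3,3,3,2,2,2,2,2
S0047,43.4385076791022,female,21.318748083359,2,2,2,2,1,1,1,1,1,1,1,1,1,1
S0048,39.3597899576021,male,18.6178381029357,3,3,2,2,2,2,2,2,2,2,2,2,2,2
S0049,41.1294772076849,female,20.8952175747851,2,2,2,2,2,2,2,2,2,1,1,1,1,1
S0050,50.835086066306,male,21.9795430520002,2,1,1,1,1,1,1,1,1,1,1,1,1,1
S0051,39.2141091364801,male,25.4140095882093,1,1,1,1,1,1,1,1,1,0,0,0,0,0
S0052,50.0594810581404,male,22.5457949816877,1,1,1,1,1,1,1,1,1,1,1,1,1,0
S0053,41.865072492565,male,25.5706467270243,3,3,2,2,2,2,2,2,2,2,2,2,2,2
S0054,42.0032818479776,male,24.9745088212618,1,1,1,1,1,1,1,1,1,1,1,1,1,1
S0055,44.2111843610518,male,22.8231106270265,3,3,3,3,3,2,2,2,2,2,2,2,2,2
S0056,41.4346408715529,male,25.3949889884434,3,3,3,3,3,3,3,3,3,3,3,3,3,2
S0057,32.7597976668474,male,20.4691239732616,3,3,3,3,3,3,3,3,3,2,2,2,2,2
S0058,41.4385404214176,male,18.7164471769547,2,2,2,2,2,2,2,2,2,2,2,1,1,1
S0059,45.3891453001573,female,21.0305155665205,1,1,1,1,0,0,0,0,0,0,0,0,0,0
S0060,43.6401481388871,male,21.5418695069123,2,1,1,1,1,1,1,1,1,1,1,1,1,1
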