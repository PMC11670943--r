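"id","taxon","latitude","longitude","1","7","8a","5a","1a","2a","3a","4a","1b","2b","3b","4b"
"E001","east",40.9230498803055,-76.2159692183343,1.61544722638499,2,"D",3,0.278533240023601,2360.08154924922,1850.87558300067,4701.37087278072,0.247199067046874,5808.92757347011,3837.22304198624,5783.15948658976
"E002","east",44.8209821407631,-73.6860198790586,3.31390891571201,2,"D",7,0.298563566614454,1859.75815095656,2094.99386929512,4563.75747210245,0.222277783272016,5522.85852400034,4414.88001945785,6691.24754254959
"E003","east",44.9463153759024,-72.6610167145967,1.53415093877146,2,"U",5,0.252774203024495,3011.09374196323,2350.67475990106,3586.01105135943,0.221639441950865,4911.61440173109,4046.18886230518,6734.71015934247
"E004","east",45.4198327285456,-73.0953124263241,1.56390307629268,2,"U",2,0.353743610313941,3052.66326632394,2048.97437079516,3938.68850416237,0.236620710104177,4779.11363010844,3943.01839111247,6366.9465813745
"E005","east",44.4109703889199,-73.3547879329364,2.86339182072481,2,"U",5,0.277604725183953,2712.69447838006,2296.71208011137,4588.53005339537,0.338043785986301,5882.61226600543,4106.01426510321,7230.42790583448
"E006","east",49.3006374670035,-76.8394036089937,1.53336619723151,2,"D",4,0.134088515667874,3382.87582262158,2185.16701937212,3588.57071699177,0.322867556515595,5691.46748751393,4431.92629611561,6952.50645839172
"E007","east",43.5636403827286,-77.8689593728777,2.22817689040635,2,"U",1,0.221637186174196,2882.4714345356,2180.53172658389,3459.31036532236,0.389681459073611,5194.12127816639,4131.95051666473,6678.33220616991
"E008","east",42.668288384741,-75.0229752970107,2.27439088171187,2,"D",4,0.193466356313301,3569.97222617163,2066.44321206073,3747.2411010586,0.211049444691236,4213.99056263117,3383.88262758457,6402.75495583805
"W001","west",52.1113936695422,-123.218325630481,1.80842777603465,2,"D",7,0.438197632703283,3952.56246901613,3140.24376411825,4846.02107872727,0.597544981705525,6631.62059232314,4687.52048743672,8231.18802339673
"W002","west",40.6485742881344,-120.021027693302,1.93477917795654,2,"U",6,0.378733944780819,4086.79143957091,2732.64521129309,5418.57449818791,0.463254912662785,6262.52902192033,5218.6249453392,7431.00435979173
"W003","west",46.2711605573559,-117.322587646835,2.32308731998978,2,"U",9,0.590078730881618,3863.40002699097,2775.99671652434,5000.41113666262,0.548360451487858,6409.18622468097,5173.67012581934,6142.13115231186
"W004","west",46.1345336191311,-117.899269946926,2.62608011125722,2,"U",7,0.455359795045912,3305.45095350232,2532.13514639623,4403.71435121389,0.36919281275662,5889.28727811982,5370.00579756067,7968.66643565091
"W005","west",45.6229354949759,-120.096239513939,2.3496891192239,2,"U",8,0.373305437980254,3730.44048700035,3048.44833145742,4523.59103099015,0.698781208773211,5623.31475337551,4467.13561396715,7623.7014583144
"W006","west",48.0759210557856,-120.685467609348,2.12832529855922,2,"D",9,0.420835432277272,3359.81843767005,2854.53672331877,5911.08366243344,0.411979343362277,5552.41449389161,4833.51331806225,7439.84136699706
"W007","west",46.9820085923271,-121.856345508154,3.0672768148022,2,"D",6,0.411233365628989,4180.55402525232,2777.45459641223,4934.77038715992,0.511436961924666,6438.95299782166,4975.64410978155,6867.26389964757
"W008","west",45.9072583821447,-120.324035205913,2.13750544375445,2,"U",5,0.449116769298376,3726.23574500336,2895.4681952019,4987.02069370012,0.503163007326286,6058.13821699388,4229.63069852825,6593.40373721957
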