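subject_id,group,ADHD_RVI,highBP_RVI,MDD_RVI,MET_RVI,PD_RVI,fat_fraction,sum7,whtr,jump,vo2max,grip,SSD_RVI,BD_RVI,T2D_RVI,PAS,WHODAS,CDSS
sub0001,HC,-0.30975954792865235,-1.4398780820654067,-0.8771643110686929,-1.7000122044442056,0.4319564566343435,0.9661927324087877,-0.6531039713974971,-0.2575266149905791,0.2120511765528696,-0.435069517027168,-0.4718740643348707,0.3113769549879574,0.13751572940170836,-0.5149399156734357,-1.2446803985205173,-0.5979337435512968,-0.7456580075351995
sub0002,HC,0.03466654221446874,1.5071613556312025,-0.05277140626033061,0.7704067994377108,0.6167060187981379,0.43186908234815335,-0.06761666747577685,-0.6722584457432005,-1.041552473722849,0.17699803000854142,-0.3579390402420163,0.7928212622950086,0.80432841749380235,1.126999858315314,0.3145884874802654,0.06993448678283827,-0.11911078257019464
sub0003,HC,-1.332747895496709,0.2940249525737926,-0.8960281874430265,-1.2038200222563715,0.7685516305812861,-0.4640350173356832,1.0616202323361286,1.5169258008786024,0.28697708201308025,-1.8059465171691924,0.33921337452935363,1.662273041629267,0.7917630980582594,-0.08253776752258424,0.17287676733432267,1.1089388121513148,0.08009174873652758
sub0004,SZ,0.5466870557268438,1.2567594325162894,0.4104821203803792,0.13039263284056002,0.5324180600901991,-1.5139156289608,-0.37854003471471387,-0.9818127164084155,-0.5702558638962538,0.516903860509166,-0.33829061533703575,0.6725742343841857,3.0681588263022146,2.0041375414955436,1.4119344653476371,1.2112469452725505,1.6470266345385411
sub0005,SZ,0.3408214281852755,-0.9368109340949646,-0.37406255058689064,-7.149898438443963e-4,-0.3614241526993126,0.196679030651972,0.8055214837689927,0.949453093534249,-1.6131617941969068,-2.2793764203386484,-1.0968024780698737,0.11470729896247611,1.5551021995350283,0.45786331567174665,1.3298288421801137,0.972204400084001,0.5478148995787834
sub0006,SZ,0.686701297395428,-0.39198805929804004,0.49462848622012606,1.064066266294017,-0.006884217857266339,0.9121665236754102,-0.47603527248950855,0.023442725599096798,0.06804819123307021,-0.8860276729287859,0.31389866393745275,0.9439601491007266,1.0141487023945626,1.1303099890484773,0.2849753353309997,0.6841992859036296,0.8546110124972205
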