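region,SSD,BD,MDD,AD,PD,highBP,MET,T2D,ADHD
bankssts,-2.265506004442848,-0.36552641758520815,-0.2962355830552848,0.5397417052258969,-0.2806191579377351,0.47285105463857663,-0.052059831069939694,-1.9957580884219626,-1.0020381555118931
caudalanteriorcingulate,-0.9934678270402508,-0.014365253472741434,-0.033585611965073814,-0.635637862369232,0.3899303494987807,-0.5194750496808774,-0.23615766943296196,-1.2501860309082404,0.2716220194115612
caudalmiddlefrontal,1.984459351153423,0.9328126010471742,0.06813716601032624,0.8897795920968792,-0.20659330219217642,0.50749160110769,0.1534534931379981,1.1605642844790578,-0.5247354500006367
cuneus,0.3999340421322264,-0.06751015269859398,-0.2822702137504446,-1.220151118842071,-0.3060007481788276,-0.5357069422818177,0.28562081011490414,-0.9028611390944704,0.03286214764317019
entorhinal,-1.3780189406288714,-0.37846834052355016,-2.7906907794290157,1.2533135797785542,0.6943427480813226,-0.3275252766814641,-1.6227498777369596,-0.48530917282305,-0.16680445807102692
fusiform,1.5387911286040443,-0.1181304823156813,0.7432657087904857,0.3480423476312977,-0.35091446606985804,-0.24025702834631538,-1.0030828266975256,-0.29589041758156,-0.9955757567611552
inferiorparietal,-1.4137238194953505,-2.204386961026401,-2.6365749337889546,0.31292288992551287,-0.19389211331684808,-0.9943607031333708,1.1116114138361348,-0.2736261533669126,1.4970413988368787
inferiortemporal,-2.254240033976125,-0.17850359734278495,-0.3086206290624067,-2.521917608655309,-1.616576213021162,-0.36575715682348753,-0.917789219676266,-2.0106006840905137,-1.0151780828855208
isthmuscingulate,-0.2769598218426157,0.7893005142235102,0.28524387843736865,-0.43873256644534936,-0.37069433287990866,-1.074702501819333,0.6415951565579072,-0.4525831441280946,-0.6654980297701362
lateraloccipital,-0.6337159119723982,-0.1795399496348864,-1.1625202584563827,-0.5414426915706085,0.12517270368923294,0.8913172953844504,-0.6645307975372503,0.20602537913962723,-1.3509087679443743
lateralorbitofrontal,0.29347465113038457,-0.4164101483034355,0.6456384346555971,1.5462027424020228,0.8050216458509228,-0.1275688291454854,1.2798215834134483,-0.8451884583295994,1.1304224909422211
lingual,-0.48519010818819236,-1.0700008102422343,-0.3574330426017165,-0.2542830761986389,-0.06957884219315784,-3.8261637154458366,-1.1986996873069637,-0.4240554457377177,-0.8782229173208618
medialorbitofrontal,-1.206701250379138,-2.04681904087165,-2.0435569858462648,-0.5884403780951918,-2.0807670289607048,-1.0836056161831389,-0.5285571687113667,-1.3612010758892028,-2.3605275559242633
middletemporal,1.5283699165850335,1.8753211892780175,0.378667051860331,1.6700198803050688,0.92887265296489685,1.6429771400459774,0.16753090117204927,2.767193947815904,2.094087599827759
parahippocampal,0.23588993411742962,-0.40043333437452217,0.34701022337465676,-1.8278492043811927,-0.4283547526631836,-0.14851263315874128,0.24171594557586829,-0.5502380722756863,0.24630263406552588
paracentral,-1.0092135778643752,0.596704153775177,-0.5846613802605036,-0.8877287805743652,-0.6479844097277407,0.6588250223569228,-0.8634057405469834,-0.8115790912836176,-0.03635494432966697
parsopercularis,-1.991548817432335,-0.6899749223637697,0.23256208246057747,-1.085717073889054,-1.4542046497604508,-0.7876204487121211,-0.6479568642591487,-0.39248635564385714,-1.2811087768998026
parsorbitalis,-0.8006199928334554,-0.3483757786303955,1.8574164274784144,-0.9750584813023491,1.1163387343969065,0.9027806201393923,-0.5447098884042795,-1.2721250285827612,0.02978881395447774
parstriangularis,-1.7173967852861256,-1.330294678426252,-1.2155399320518907,-2.808119655150499,-1.9563145468225234,-1.8111611740008027,-1.1879904548593643,0.3283263542722513,-1.8568506110265168
pericalcarine,-1.1440871191389077,-1.2560516344141137,1.5728386695564751,-0.5139159575769638,-1.6416810030228939,0.9868584237759392,-0.6112503435900744,1.309987416369902,-0.7849399376325119
postcentral,0.4600193831690937,1.4173723045052968,0.27578715529241155,0.37028503366047005,1.877742248217966,-0.11352108674761388,0.2059470969810423,1.4324806806625854,0.27065241636195475
posteriorcingulate,0.39537511489026694,-0.6295680453080418,0.8965188751131771,0.28356906144541744,-0.7749345293479062,0.4839391634324389,0.7762963514937152,0.996418670950718,-1.0071685751147366
precentral,-0.9587806398650852,-0.5241267116712423,-0.33517298565127374,-1.0342600038423022,-0.47374331214037174,0.4374056092468293,1.1902856730956157,-0.8566916712442574,-2.5294668243362417
precuneus,-0.20523113798554946,-0.04598763668526002,-0.7366799587673125,0.4419564692407309,-0.5003097504977431,-0.46561911659979427,-0.9513245514218834,1.2397955366135966,-0.014556015894239206
rostralanteriorcingulate,-1.9931790064406296,0.04444210905604638,0.400594296915374,0.2976868398065315,1.4460520123021852,0.7000673224912776,-0.14244409001140748,0.433141949897515,0.22625457088331433
rostralmiddlefrontal,-0.8364381291430133,0.14191434902203973,-0.9823736987677129,0.23173946035003917,-0.44275134692694057,0.9322719762397534,0.14502753183466918,0.4185680017285565,-0.5988357358776916
superiorfrontal,-0.8157292079296121,-0.40615138702691733,-0.2818815313140194,-0.054520669740897636,-0.16410102498973703,0.11539556892071574,-0.2753119840576127,0.39362253509963685,-1.998905662122324
superiorparietal,1.0156328674454813,0.002831070130724388,-0.336690973294801,-1.1561916102590006,-1.0725980038691854,-0.5406000207143575,0.15757668813612025,-1.8574001651496073,-0.7962380902673718
superiortemporal,1.0319698128329442,-1.2652418841325463,-0.47127172345141083,0.7723917910920557,-0.7129613167053458,0.21397229666770515,1.2523946795240777,-0.3046557346675474,-1.1793727873854605
supramarginal,2.080290352016129,1.032960538027308,0.027102676111495572,0.11950641782548278,-0.3566079067888215,-1.2731688551972373,1.2496777000294952,-0.7348875777908782,-1.5846238198124971
frontalpole,-0.4312062496814519,1.7272140043326392,0.30075947342201803,0.7257327931507893,0.13324215781196247,-0.5245716081636869,-1.8505968435807563,1.6738266499471195,-0.5016587964190051
temporalpole,-0.10818943136541823,-0.4601309026648492,-1.3818082701915355,1.3305788115228352,1.141776693328008,0.8025879169824012,-0.14885358020289252,0.6022379032978492,-0.11454109923584839
transversetemporal,-2.1241127543772342,-2.198189934727665,-0.15679598258832783,-1.296772426869331,-0.8250743038102772,-1.6775363583809328,-4.184680640916704,-2.261827448924181,-1.3553719202357652
insula,0.7177551794926628,0.380041897733889,-0.23475495920112313,0.26778374300576974,-0.8027543011808818,1.1527294973262394,1.9842000512173128,0.39059147727578414,0.5751232569811859
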