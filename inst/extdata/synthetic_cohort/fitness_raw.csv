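subject_id,group,age,sex,sf_subscapular_1,sf_subscapular_2,sf_subscapular_3,sf_subscapular_4,sf_biceps_1,sf_biceps_2,sf_biceps_3,sf_biceps_4,sf_triceps_1,sf_triceps_2,sf_triceps_3,sf_triceps_4,sf_abdominal_1,sf_abdominal_2,sf_abdominal_3,sf_abdominal_4,sf_suprailiac_1,sf_suprailiac_2,sf_suprailiac_3,sf_suprailiac_4,sf_thigh_1,sf_thigh_2,sf_thigh_3,sf_thigh_4,sf_calf_1,sf_calf_2,sf_calf_3,sf_calf_4,height,weight,waist,hip,hr_level1,hr_level2,hr_level3,hr_level4,hr_level5,grip_left_1,grip_left_2,grip_right_1,grip_right_2,jump_1,jump_2
sub0001,HC,32.88536177063361,1,9.300799202663391,9.428797726395178,8.94152938704548,9.575669553790133,18.14004753855026,17.551170629476573,17.330229154676314,17.46867863285631,23.04844662008332,27.283791105708065,24.76557720809797,24.92070385610112,16.111816114131567,15.411563921701218,16.91153572167247,15.970740591913813,21.64226392487072,20.53059144553847,19.68307676876438,21.02164624325552,17.79165934872375,19.48573770182959,18.946884834432037,16.753717114173835,11.680998542994821,11.884849870259325,10.76682223651108,11.224785838733771,178.15886738813066,85.51845097015052,69.2809900722608,107.25039899534573,97.14766612970801,109.74659531282853,125.14391159195264,136.34619009532213,148.8062899866536,39.9669841520092,41.36062332793515,44.67184694013294,42.970806596503465,172.94873481119802,169.9303622240304
sub0002,HC,58.282976193353534,0,14.631203722807834,13.195523329970385,13.937845252551513,14.779852326099668,13.347495602526546,13.335656011679445,12.139527925500564,14.558773250179428,16.311300038133908,14.530462803600717,14.883534662702194,15.719418872199887,7.628178931669545,7.15415959330046,7.55155755540054,6.989536994883875,15.301124126607435,15.78379654407931,16.161750401996443,16.231980846362262,7.280880855168049,8.30956934293102,7.921635277142174,7.68198777381131,20.752968950565954,19.51349988782398,18.98135534160874,18.676975138078927,155.1373563813625,72.82073647198834,91.31025359227988,92.74143967403826,83.08717261573788,99.24982991414255,111.98486710862132,128.55177582085088,141.81595344229405,34.74428448621211,35.74737145370993,35.599921203052055,38.99938833808709,197.5815910015399,196.42938923037593
sub0003,HC,36.77658567158505,1,13.003838790963904,14.229125338863621,14.830988680350718,13.544941909391289,13.432334959438624,12.85981514432188,13.446463760721365,12.896344613599439,15.220817885776125,14.879357365570678,15.703608450119445,16.084433147468097,27.711370370705207,26.449445640627264,29.645532264404586,28.68746599198536,17.55483125091904,18.65596495902226,19.22909246501716,18.819499561449494,11.331548515139112,11.405537107727785,11.943053096522224,12.155690795737986,9.691712552506225,10.252996670463393,9.632182104166843,9.953702477635392,171.5340957423726,66.1162467899646,92.29263434542136,97.76340451977138,102.1343569522061,118.02826110859142,133.20010101312397,148.9151947291533,169.4389072114675,48.437759035240816,49.86143489551392,49.219251510963105,49.4124368771831,184.06680673494577,181.96675060176105
sub0004,SZ,41.18931542756036,1,18.257476624454718,15.861508741442302,17.217091793641146,15.075009653709458,19.18424654966926,16.408115032476484,19.453821628694588,18.5765212001542,16.66651964871735,17.584866578078326,17.515622551997836,17.836656187672453,28.348451276447015,27.65214173106507,31.183772735110754,28.299589315331605,27.995003631016296,29.326753458437395,27.46471269883822,27.347418345891118,18.413352265421945,18.650533994378723,20.650802575761038,18.28441249227899,6.377623924409512,5.907362087333069,6.326546984487871,6.725697279691577,173.80700282353078,91.45771404128344,93.8738770646154,104.74712494096671,98.9955216797092,119.28019225162365,137.47975278732554,153.6845322354791,169.51002281423285,40.42998694578916,40.5585089676161,43.55984209969993,39.828373288953095,142.17696556168687,150.82347978185157
sub0005,SZ,21.56061936635524,1,24.227483068873415,23.393242053893545,20.959386204962573,21.730105203464554,14.927560133213612,15.753636602798538,15.990469952912726,12.95477214414999,19.6906331989506,18.650383161948593,19.127601543626046,18.961246106225836,10.396505272543347,10.416740753656198,9.704503520585861,10.569138484809331,23.284418718592065,21.85997579556179,22.065848259797342,19.817923783437326,26.085389286602716,28.8028275883432,24.64275651758889,25.943016001405876,10.758768106517143,11.039713566612182,11.176414937221717,11.413375340371037,170.85673840594225,77.02636443355775,93.0924332459647,99.67658619582866,89.97590973469002,112.24734493519058,NA,NA,NA,44.39394018580807,44.15540874613038,47.261694937703005,47.04544471618963,161.01044825000244,168.65546227768974
sub0006,SZ,34.73245178628713,1,23.82991894903963,26.60291179125739,22.38617443691287,27.346110652533717,14.971283141627511,14.284097908692754,14.3712721722914,13.700160156836725,17.473551143999842,16.63075726112981,16.257999114140052,17.5970577176011,12.37715363453295,13.187839572156252,14.455423100683788,12.524997484054913,27.686028809694626,29.211378338398283,30.63446010379726,31.71372091270197,18.308165873773998,20.247650005805227,20.030435058946065,20.060958368253637,32.509750962275774,32.6559221652785,31.823539642741256,31.095109153476795,165.49690078917536,95.93638178173427,114.36646549557439,112.7745062769167,108.03942637623227,124.56064594741906,NA,NA,NA,49.85423878877563,45.235997433325046,49.172305037420955,48.98027123721728,151.14370828446317,159.5106396700461
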