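subject_id	lh_bankssts_thickness	lh_caudalanteriorcingulate_thickness	lh_caudalmiddlefrontal_thickness	lh_cuneus_thickness	lh_entorhinal_thickness	lh_fusiform_thickness	lh_inferiorparietal_thickness	lh_inferiortemporal_thickness	lh_isthmuscingulate_thickness	lh_lateraloccipital_thickness	lh_lateralorbitofrontal_thickness	lh_lingual_thickness	lh_medialorbitofrontal_thickness	lh_middletemporal_thickness	lh_parahippocampal_thickness	lh_paracentral_thickness	lh_parsopercularis_thickness	lh_parsorbitalis_thickness	lh_parstriangularis_thickness	lh_pericalcarine_thickness	lh_postcentral_thickness	lh_posteriorcingulate_thickness	lh_precentral_thickness	lh_precuneus_thickness	lh_rostralanteriorcingulate_thickness	lh_rostralmiddlefrontal_thickness	lh_superiorfrontal_thickness	lh_superiorparietal_thickness	lh_superiortemporal_thickness	lh_supramarginal_thickness	lh_frontalpole_thickness	lh_temporalpole_thickness	lh_transversetemporal_thickness	lh_insula_thickness
sub0001	2.649533736338611	2.6401779952391498	2.535536839715027	2.5668066539474927	2.6250353607787864	2.520474042844803	2.4267591545402554	2.346408831656083	2.426883475612512	2.6116032360671877	2.6482149931928616	2.514704150833209	2.736537864382679	2.500248226031243	2.6370141781222127	2.592895119005765	2.5763985285715436	2.6897517213264965	2.6061120984011805	2.452966517526888	2.5863136548220766	2.409331764395132	2.709848849201398	2.728584724569209	2.526478311646373	2.6961290129258275	2.4194080332630885	2.6015927326003974	2.698358158820507	2.4003502870382496	2.4869710327775043	2.4750811863230404	2.5847325513755766	2.4742138390647788
sub0002	2.3398491023169354	2.3369049141436937	2.3914475671999216	2.486069720352393	2.3057892698243823	2.2887250704928963	2.382498906849128	2.4742234813531034	2.4827023345539976	2.3420542222917717	2.2984827717526697	2.384524479003394	2.5739520786065784	2.320832220724638	2.4984184016205364	2.452338202523402	2.3967675868682434	2.384420411254456	2.3617122178832948	2.3841161598599196	2.393882006968648	2.421961838963032	2.2704366787841783	2.2798486844658425	2.3118274955779685	2.476074601692847	2.3107737308623015	2.339561828342363	2.2942564805599317	2.267105438999398	2.3976702099003004	2.3676675112779617	2.3682228694429637	2.32144631498804
sub0003	2.4293622373917665	2.37793778606163	2.4593848378956724	2.5236929863480264	2.7374758560662755	2.5741496238474104	2.560950593284078	2.700787418672598	2.597203862988378	2.406601645546752	2.518774802385583	2.607427524631455	2.5592381701838987	2.503873106583241	2.424773478363319	2.6873840400308877	2.484954034229572	2.5326702571394204	2.417775484405066	2.5006616458821207	2.480274314191706	2.632168022345999	2.5423224032563585	2.4571365084467454	2.4458822661103174	2.646705305343488	2.470075117133243	2.593989026440271	2.495970147373161	2.7098735434462595	2.535337022877106	2.7100438398661377	2.5929642893391383	2.5891387785319497
sub0004	2.4773347229780085	2.509160919450957	2.436544532108953	2.628215136671533	2.5853625791597814	2.589918259712689	2.4748524814639943	2.5447494886002415	2.4359386237883514	2.4600747075804086	2.4921058948925925	2.467693561887006	2.621744367652615	2.6422090014841797	2.4760220997250566	2.2418679399158736	2.626814316150743	2.6613066969223618	2.4125517074448557	2.4644923775890213	2.437329471590311	2.6354916508895125	2.3930152471053483	2.4413367910844213	2.362205185809963	2.3641869611442177	2.398988710924574	2.5720401519562643	2.343004192052944	2.461546004826893	2.6197473608223754	2.543746271576094	2.3631875449668223	2.8039510628860556
sub0005	2.611900782259318	2.6739420366800073	2.8585320665213785	2.4169481645077977	2.478851137435065	2.6202267679506637	2.7355875844514577	2.888799721307732	2.409116280088134	2.598912244801452	2.5419270190167866	2.5523313195181236	2.8292063909064433	2.5432098029827266	2.4838524594334515	2.7545905899781618	2.605707205591863	2.5955245708147245	2.5130242387196153	2.5124490630049814	2.4523508967886447	2.6320191638235775	2.5301944800919136	2.668077038268418	2.6124541802458645	2.6291103107398635	2.6281232625297886	2.532864228619321	2.51944687419335	2.690018475434332	2.3559240875632166	2.6505827012601206	2.5247080737368446	2.6426287969883924
sub0006	2.4198516723662875	2.449488182175303	2.551600116325267	2.5089097397381885	2.5692390987170795	2.3930121089163654	2.4360598503153135	2.5242208262211268	2.5479820468223653	2.3345284023792425	2.570329390722101	2.409774837731768	2.418970808205359	2.568751027840498	2.460639423092715	2.5030796631688745	2.6127992265853464	2.6223313511163973	2.4156853516333014	2.4469954889324472	2.535093591404253	2.4003460171570326	2.4243181395704756	2.417394170866253	2.5098328051456034	2.469004032892759	2.4413191105835144	2.503864893487582	2.633873771797366	2.5822070426804293	2.456309114691093	2.694551549500168	2.4763702551741043	2.7189042842111983
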