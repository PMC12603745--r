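subject_id	rh_bankssts_thickness	rh_caudalanteriorcingulate_thickness	rh_caudalmiddlefrontal_thickness	rh_cuneus_thickness	rh_entorhinal_thickness	rh_fusiform_thickness	rh_inferiorparietal_thickness	rh_inferiortemporal_thickness	rh_isthmuscingulate_thickness	rh_lateraloccipital_thickness	rh_lateralorbitofrontal_thickness	rh_lingual_thickness	rh_medialorbitofrontal_thickness	rh_middletemporal_thickness	rh_parahippocampal_thickness	rh_paracentral_thickness	rh_parsopercularis_thickness	rh_parsorbitalis_thickness	rh_parstriangularis_thickness	rh_pericalcarine_thickness	rh_postcentral_thickness	rh_posteriorcingulate_thickness	rh_precentral_thickness	rh_precuneus_thickness	rh_rostralanteriorcingulate_thickness	rh_rostralmiddlefrontal_thickness	rh_superiorfrontal_thickness	rh_superiorparietal_thickness	rh_superiortemporal_thickness	rh_supramarginal_thickness	rh_frontalpole_thickness	rh_temporalpole_thickness	rh_transversetemporal_thickness	rh_insula_thickness
sub0001	2.678847264391559	2.6148274482717495	2.5456822565717103	2.5944849501601377	2.653984922102654	2.498456430028995	2.430946983440456	2.3498861671302302	2.4364432732136696	2.6082737863953662	2.6498258936538157	2.5186951168243175	2.7251415585899004	2.475392536571795	2.602140089366373	2.530588791114659	2.609688496806339	2.676926300756243	2.6276453494287395	2.456695360534063	2.5452448433681334	2.3814633471883693	2.7265953079569774	2.765605756367425	2.478968023055896	2.6833342331884054	2.392268631770859	2.63331486368663	2.6796619387326945	2.4030663258816736	2.452380982152391	2.4705334211166328	2.6171660328850024	2.4648292093067883
sub0002	2.300511682191906	2.3425738544152743	2.388309519548763	2.5515846916341265	2.3263703210818303	2.251976586308212	2.4094564987219798	2.4897474711155088	2.4752205915796957	2.349357668821552	2.290482377615705	2.401250092569619	2.587903556821715	2.3185331998348735	2.495857839309553	2.482383744512944	2.39562923283917	2.3938078497757727	2.3160218279381124	2.4153633760718916	2.389580066897926	2.4227079753556313	2.217557592711264	2.22987875265219	2.333460298539927	2.4295062994011776	2.3346322207816828	2.3504643617968486	2.3038173560125252	2.2807422238926542	2.377768358901755	2.3704674848657814	2.3736180545257475	2.3409789423310574
sub0003	2.4383177718173275	2.3674848997992117	2.456566821835574	2.499532296364842	2.747419086482916	2.5385828493706253	2.6046795090768065	2.671635929382832	2.6245646156741413	2.418035647954165	2.5096783058909518	2.639081578869109	2.543604168867961	2.4985996555030066	2.4113783548193255	2.709083732765969	2.4944271895231025	2.5578332992403037	2.413484847113166	2.5010430522390847	2.532407387741966	2.620917224685361	2.5050831046516984	2.45030528465747	2.4897285221555796	2.633255323092806	2.4730716168888827	2.591757277743672	2.4669187488499364	2.698315846677157	2.5666882055655615	2.7310722247098655	2.566945164035023	2.5972905732632223
sub0004	2.4310375717430115	2.438254024487934	2.43937072351834	2.6343371701585445	2.5637148764205024	2.6124600752070357	2.4888072848500498	2.546717526484916	2.437482903665166	2.430811942255036	2.4783224587701764	2.4712183207932017	2.591882164251564	2.6768853655324683	2.4995406239004354	2.2338783635505925	2.6448693193391573	2.6796687414142246	2.400941385037962	2.4553715045039617	2.4377207741497946	2.624621161606678	2.3817911828600806	2.459963378200813	2.3592666552343484	2.3834395581538006	2.390373931412948	2.564080210518882	2.3168815722711424	2.4670315333368933	2.5655546596056293	2.5852315918109867	2.375933445255226	2.8092067633517406
sub0005	2.6162945455230915	2.684718083416844	2.8333303765909688	2.4410164066685476	2.5389240376486732	2.6671910950915287	2.7162111919879965	2.857559060396454	2.4045191216357624	2.637812513210273	2.5657824189540417	2.5386204291264263	2.809065945875141	2.4915963614522276	2.518444510417513	2.7901817355679777	2.5795896550333923	2.671460053635028	2.53759691038329	2.583662234081459	2.497011995711968	2.618271918296956	2.5368267134488627	2.683651971602632	2.6197169444843253	2.620370497963261	2.6063784880277834	2.5771524144619153	2.491074662000965	2.6836466320113237	2.3630080339633164	2.7103620068146657	2.52187570701519	2.6089253452364827
sub0006	2.4217933880644855	2.3936350126631676	2.510410913489227	2.523336481302438	2.5808697399272194	2.4028258014113457	2.4482705836327123	2.4491275005174655	2.538114992750324	2.3199002677824674	2.5921247596093036	2.4336978429924407	2.4098348131642777	2.590135173286222	2.4925493763312883	2.46651128938965	2.622974401694469	2.595975323412459	2.3831074791182374	2.4329988439150863	2.5610624647426503	2.390750578148114	2.4151537962271306	2.4281342770166465	2.5518107524334956	2.470444121757535	2.423112211327977	2.4722545820227553	2.598419477557713	2.6014789733260266	2.4618974697539544	2.699254138295752	2.475356999126859	2.714925950558852
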