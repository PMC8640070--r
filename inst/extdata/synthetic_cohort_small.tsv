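sample_id	label	aao	pc1	pc2	HLA_B_27	HLA_X_02	HLA_X_03	HLA_X_04	HLA_X_05	HLA_C_06
S00001	1	71.18782229116466	0.9830641419764863	2.000434492087953	1.9644415748743016	2	0.9764985563861361	1.0345270182590482	1.9989428024072933	1.0344440622855853
S00002	1	26.513431983607425	-0.11018933145931346	-0.8294263359111667	0	0.09240458222720299	2	0.9382990415908512	0.9705095188161618	1.9695231556151678
S00003	1	17.610991562750893	0.15868039144046586	0.24621020802045623	0.9641605546099791	0	0.9871305102140808	0	0	0
S00004	1	23.659954235494233	-0.05493850304693007	-0.10477211883229366	0.9982123877062915	1.0313865124675983	0.9709099995802654	1.0103211538253711	0.9452296122004346	1.0581666904514184
S00005	1	54.230367538226545	-1.0781371513286024	0.7325674543569313	0.010849737322934441	0	1.0136227633280799	0.01380548148494194	0.9	0.02719990906131361
S00006	1	51.118062835039105	0.715442888537523	-0.8044322802438773	0.9680278269161269	0.9267302861302678	0	1.011054178092895	1.059333112352883	0.9601956421292513
S00007	1	53.61841436041529	1.0634419345546897	1.5751807773152309	1.0337137146684876	0.9078744221033374	0.090623427051345	1.9558072358983505	1.9708474587019273	0.9
S00008	1	41.449871136127285	1.1098851925530733	-0.10187842798778207	0.9528221073413066	0	0	1.068675448740939	0	2
S00009	1	53.30479563592795	-0.24974070204936322	-0.4325781083394695	0	0	0.0387629656531263	1.041750868383432	0	0
S00010	1	40.12247532942692	-1.42399202362308	-0.2927710065136571	0.029312758658383894	0.015876512306701226	0.0017256352372941172	0	0	0.04134132887448863
S00011	1	68.01670903946233	-0.16051518119528135	1.4596046579931374	0.945886093099871	0.9676851789678914	1.0427492239196814	1.0377852330812327	0.95650793863834	1.0547245228421083
S00012	1	59.464074573351624	0.9142084279699402	-1.3844452407625711	0.021317131427329352	0	1.0327944814582288	0.963355389854983	1.0061628658009725	0
S00013	1	32.26657087377051	0.19855200562536318	1.4156266778580278	0	0	0.0588903230905303	0.004481307343000033	1.08594810438754	1.09560740149
S00014	1	41.97224693838708	-0.766234429954565	2.098684067750589	1.0452828372951732	0.04424426997023869	1.003591750596783	0.04010597373486124	2	0.1
S00015	1	36.25495205738479	0.012579368908290034	1.444874781623074	0.9678384481426588	0	0	0.9631071886685103	1.9692307855052236	0.9154093155472448
S00016	1	37.40057269186611	-0.6151382981597112	0.9807969759915663	0.9216951774712636	0.05961313374554838	0.9150080996071801	0	1.022900816309217	0.04378583535019646
S00017	1	40.658360227288796	1.017822916966301	-0.9162271181287905	1.956867934072451	0	2	0.9661462676392637	0.9787924972126237	0
S00018	1	67.19738300693697	0.43323566148671766	0.9881642560601561	0.04171190920682491	0.034125881670287316	0	0	0	0.062145229531711255
S00019	1	53.42788851867476	-0.7470868829183475	-0.8936556735803987	0.1	0.045511860260723666	0.038666307148626594	0	0	0
S00020	1	29.865488171314695	-0.5317324244458924	-0.5912535540126147	0.0641879189591205	0.04467892420969136	1.0177511724611623	0	0	0.9490031759298689
S00021	1	20.848482590573113	2.5399107828434357	-0.4450267517867669	0.04797744426456042	0.05745897206611336	0	1.062139611786402	0.009182726406557274	1.9966185809355876
S00022	1	41.48654034864995	1.0762689978970787	-0.4003210409084218	0	0	1.067995745112109	0.052800328726056424	0	1.0163129196390503
S00023	1	28.73254596756646	0.046717442892111494	-1.2249937736722367	0	1.0007399630076947	1.0428972584727398	1.0061054934726974	1.0299386556023613	0.0032664224929060647
S00024	1	74.41764157522533	0.0780153337417383	0.18860700260702165	1.0098961396023047	0	0.9030615524540215	0.030377410882525276	0.9761968034800099	0.0271784485793731
S00025	1	38.74363248804308	2.0170099510303223	-0.4094205279723138	1.9718747728013648	1.0045863446684387	1.9739852567251843	1.9757741114824539	0.9992329769318665	1.0582934430716684
S00026	0	32.38790680609789	0.5411537365506569	1.562094327396967	0.037189316711760526	0	0	0.061729870049817614	0.9810521058280353	0
S00027	0	3.247393846527018	0.31002978158488137	-1.1273347529080873	0	0.06496678760872314	0.03956805264226579	0	0	0.9445402735883962
S00028	0	12.077244301139821	-0.13371276145970323	-0.8565452499688246	0.012384754234145283	0.9	0	0	1.9661592358041302	0.999615144766565
S00029	0	33.44716321682516	-0.9107200427392819	0.3059985292847024	0	0.006653342829506966	0.053421778645298706	0	0	0.03529251776700225
S00030	0	28.616660959214116	1.5458681260544216	-0.6945075888215133	0.012104131418727258	0.009440640328804772	0.9924068512791854	7.167560330989355e-4	0	1.938528169498113
S00031	0	30.43470504105946	0.0194957852594152	-0.24765259587799104	0.0750949961495778	1.050016505449992	0.9913934250014137	0	0.9466129237321189	0.024320374717880372
S00032	0	1	-3.2059579423307887	0.24098858574676346	0	0	1.0105924438993978	0.027058118666489557	1.0455758691578063	1.0058642578048906
S00033	0	17.55809550327465	-0.581512384488076	0.01182476432577224	0.0665086069215197	0.028048590292270966	0.048194055120527816	1.02194284781676	1.0175044124404233	1.0618988315716136
S00034	0	33.56472601329327	-2.319995249621408	0.049525488290703974	1.0825608521607581	0	0	0.0059025760990013935	0	0
S00035	0	14.96197434704613	0.6906131784230232	0.9925887769565943	0.1	0.006453578967044214	0.020279516429864725	0.9226380236586509	1.088123526843087	1.9678025241056947
S00036	0	1	-0.904770955130827	0.06809713277909334	0	0	0.03493979985298534	0	0.9852558278947476	2
S00037	0	2.5810872876985123	0.5216267955014744	1.667102712613906	0.9397182460357325	1.0973504786050292	1.9390543208723703	0.9995596095480652	0.9482119751795984	1.9529568117349645
S00038	0	13.258644492020025	-1.0010712778314184	-0.5791248756451639	1.0645291063347728	0.08827262859242441	0.015036945506439463	0	0.0344128642463365	2
S00039	0	11.506588216151677	-1.7793918461624494	-1.1375781747353777	1.0563773367342255	0	0	0.030278508332492477	1.0433864439677765	0.9390738686215598
S00040	0	11.5049458578534	0.5815579454743759	0.46316562687686014	0	2	1.0682522023104608	1.9941478025839179	1.0089825418114684	1.002396936597118
S00041	0	30.288499812452457	1.0717607482751017	-0.6059408733094783	0	0	0.9480920273830511	0	0	1.0848719184289457
S00042	0	33.506032134674356	-1.4573003331013314	-1.0715964585266011	0.009467667284923507	0.023479486238513467	0.9961962918092109	1.929467092952349	0.03956719591013341	0.016979309620364483
S00043	0	15.366331910568448	0.9702774106252171	-0.8729900298323667	1.9551714531942936	0	1.0359514673057724	0	0.9900725779316765	1.9309662879242044
S00044	0	31.028306961332596	0.1520699903516315	-0.5473303094528994	1.019809048302564	0	0	0.9866907603420272	1.0311277337000924	1.0878579871103378
S00045	0	17.077412720447974	-0.9012338742510957	0.6250769096409945	0	0	0	0.9708691754758545	0.9481574355020682	1.954455843405542
S00046	0	14.534158659601868	1.7333997155890417	-1.0768897994208786	0	0	0	0	1.9653068280938808	0.9840866156605828
S00047	0	60.481926139120276	-1.2026845339717498	-0.7861944954438611	0	0	0	0.04212496664285663	0.9843587588518941	0
S00048	0	18.914950701026246	0.5510421554353878	0.5084440700738401	0	0	0.026806009894745728	0	0.06367003920106662	1.0013074823102686
S00049	0	56.22737103637816	-0.8853050436417828	1.6283028929589234	0	1.0245804561192045	0.9063422644866698	0	1.0139690635110825	0
S00050	0	36.82514964312362	-1.3190072809587967	0.1069577989610073	0	0.05071833319162791	1.0152168418323766	1.9539197215607857	1.0392045339579647	1.0993588196427728
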