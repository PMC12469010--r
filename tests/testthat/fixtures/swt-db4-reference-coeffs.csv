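d1,d2,d3,a3
-4.964281360261709e-01,7.172553201913324e-01,-4.828774938374265e-01,1.254162254826110e+00
-1.653566355099509e-01,6.017133078458957e-01,-4.331517967420437e-01,1.424698941468977e+00
1.506943008285011e+00,1.400693143797378e-01,-5.201409336398112e-01,1.538546068106239e+00
-1.757033445111934e+00,-3.456722434105292e-02,-1.217025930313016e-01,1.551860535560525e+00
8.193042114280852e-01,-9.202406972303273e-01,4.429745855521316e-01,1.534426463147879e+00
2.627112453973796e-02,-1.018537232232539e+00,1.777727098566591e-01,1.641826228846804e+00
-6.188141679272904e-01,4.151866761742888e-01,2.124242300771551e-01,1.711779618026251e+00
4.097425139526616e-01,1.601754277435278e+00,2.948086922078462e-01,1.663023025776882e+00
6.160066492982184e-01,1.010605685533337e+00,-1.546882021012470e-02,1.620425354432204e+00
-7.861539464788474e-01,-1.195777025900132e+00,-2.715362062610246e-02,1.596254691684989e+00
7.945587617358941e-01,-1.692414416116154e+00,-5.537796691389701e-01,1.547941621876721e+00
-1.611340459230063e+00,3.789464340960980e-01,-1.309456684169402e+00,1.659695089661697e+00
9.874779922146180e-01,1.131834659314385e+00,-1.154386338293200e+00,1.822454526297997e+00
8.531411090770636e-01,3.151597667877449e-01,-4.790668054848371e-01,1.910940162540891e+00
-8.228878771093383e-01,-2.652689412756996e-01,7.639530926870890e-01,1.961841495391881e+00
-5.416787260908085e-01,-9.844780136745901e-01,1.904091294835298e+00,1.926979795351284e+00
1.048543794148653e+00,-7.565369695141524e-01,1.888691659369406e+00,1.925334362641302e+00
-1.191044150949291e+00,5.736147835517005e-01,1.002940609338714e+00,2.043737497311746e+00
9.538460275580917e-01,1.362197350180560e+00,-2.566100978992394e-01,2.208736887984096e+00
2.025546633522971e-01,1.517924332206392e+00,-1.039070444957883e+00,2.266616046822830e+00
-6.621799846398063e-01,2.260451397658583e-01,-1.100452135745100e+00,2.136466019480947e+00
7.295423644329857e-01,-2.323966125935362e+00,-7.425088815633842e-01,1.850243246236155e+00
-9.380255710773240e-01,-2.427957055821468e+00,-2.860320955973261e-01,1.601885881469979e+00
-5.336485199034184e-02,5.445735555724567e-01,-1.706061629428480e-01,1.523340703279840e+00
1.406367663142255e-01,2.106627462512944e+00,-1.427036457208568e-01,1.395177765245976e+00
1.107575531792575e+00,7.168797864407521e-01,1.709373629713082e-03,1.157543876078472e+00
-2.839382870109706e-01,-3.880028094092347e-01,2.049862953116377e-01,8.516262698887996e-01
-1.298972865549274e+00,-3.659236467683492e-01,1.940302716284139e-01,4.972035864374448e-01
8.462144822484249e-01,-5.976517926646934e-01,6.446197962090397e-02,3.789526507254029e-01
1.999244246918376e-01,-1.464927305263707e-01,1.553761538712251e-02,5.537636455153482e-01
-5.140993690294402e-01,9.373312722125078e-01,3.965229254475586e-02,7.452378655599936e-01
4.489255257748973e-01,5.148150160521013e-01,6.899511621473372e-01,7.811438967173456e-01
-7.128083565491597e-02,-7.989563288644496e-01,1.369159525027716e+00,7.760699328834837e-01
1.827250204514172e-01,-8.524245876661564e-01,1.355762882963274e+00,7.326626615020635e-01
-1.227527391679878e+00,1.857337762654807e-01,8.353490761428979e-01,6.976303015885683e-01
1.587745667840795e+00,1.087242721785449e+00,-3.252861489857616e-01,8.118993982134159e-01
-8.715744584327348e-01,6.902102514405740e-01,-1.544133003258793e+00,7.591975437997889e-01
6.591152275369669e-01,-6.159356904997120e-01,-2.060270087919484e+00,4.338709106223176e-01
-4.333592467176844e-01,-4.256652174632196e-01,-1.762692169128802e+00,7.747054944897760e-02
-4.994656162312289e-01,1.052561743727825e-01,-9.773665187848933e-01,-1.989194632138100e-01
5.615587879085187e-01,-1.399743593201358e+00,-1.295113936286807e-01,-3.818683235374413e-01
4.134619403453013e-01,-1.291960269876451e+00,7.168955427760189e-01,-3.608009055777586e-01
-1.185113691218632e+00,1.836216657854258e+00,9.466755662892880e-01,-2.042442689745882e-01
3.037765667335878e-01,2.171175924856151e+00,6.417580551753367e-01,-1.564886316634278e-01
1.705965631775443e+00,-6.983596548219654e-01,5.575727969496341e-01,2.968041347228360e-02
-1.352175827918264e+00,-1.038896085700291e+00,9.369296703414366e-02,4.264707147338002e-01
-7.570917743654547e-01,3.971971993814449e-01,-1.041849717162098e-01,8.200110855782528e-01
6.033904974968139e-01,8.778619872279467e-02,5.498961138559340e-01,1.260945558574489e+00
1.398315975506854e+00,-1.973307132808046e-01,6.958671530436881e-01,1.678159782674452e+00
-2.089794639507868e+00,-6.140116045960188e-02,7.606089843403151e-01,1.789595059740405e+00
1.012787365531764e+00,-7.897046797548157e-01,6.419148775452367e-01,1.694705029941700e+00
2.181431305832369e-01,-2.017691406283951e-01,-4.362448066280629e-01,1.649679583848794e+00
-9.978290028686598e-01,1.410758542209509e+00,-1.018807145258797e+00,1.454059451489557e+00
9.899959882076291e-01,1.254095327821869e+00,-9.757869167746889e-01,1.150121277817274e+00
2.806511454836849e-01,-4.747783558972749e-01,-7.368698238612787e-01,8.758253023142279e-01
-1.005832288732727e+00,-2.180931004516724e+00,-7.618713686749712e-02,4.409561786122517e-01
3.774274647672459e-01,-1.306185925218148e+00,2.501474663723877e-01,-7.539410120398216e-03
-4.629998565960793e-01,1.617095028130429e+00,1.025077761212143e-01,-1.237701031632061e-01
1.499058080610796e-01,1.600955805553477e+00,-1.713702537860548e-01,-7.502019136584787e-02
1.835631198549720e+00,-4.735608624883957e-01,-4.551480610199875e-02,-2.054388983559211e-02
-2.127149429035650e+00,-2.730076665442948e-01,3.194648100171115e-01,1.446846506318317e-01
1.440631437138800e-01,2.295283824620390e-01,4.905096476633672e-01,2.926855327330968e-01
7.789352025766365e-01,-7.564202958916352e-01,7.467245841696317e-01,4.658699212561245e-01
-7.229218122522256e-02,-5.309402169258104e-01,2.268997126194832e-01,8.624520239474037e-01
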