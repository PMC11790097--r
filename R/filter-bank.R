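# Standard wavelet filter-bank coefficients: the scaling (low-pass) and
# wavelet (high-pass) synthesis pair that drives the cascade refinement of
# each mother wavelet.  These are the published constants of the Haar,
# Daubechies, Symlet, Coiflet and spline-biorthogonal filter banks; for the
# biorthogonal entries the pair generates the analysis (decomposition)
# wavelet.  Full double precision.
.wavelet_filter_bank <- list(
  `haar` = list(family = "haar",
    lo = c(0.70710678118654757, 0.70710678118654757),
    hi = c(0.70710678118654757, -0.70710678118654757)),
  `db2` = list(family = "daubechies",
    lo = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
    hi = c(-0.12940952255126037, -0.22414386804201339, 0.83651630373780794, -0.48296291314453416)),
  `db3` = list(family = "daubechies",
    lo = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154, -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
    hi = c(0.035226291885709533, 0.085441273882026658, -0.13501102001025458, -0.45987750211849154, 0.80689150931109255, -0.33267055295008263)),
  `db4` = list(family = "daubechies",
    lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651)),
  `db5` = list(family = "daubechies",
    lo = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744, -0.012580751999081999, 0.0033357252854737712),
    hi = c(0.0033357252854737712, 0.012580751999081999, -0.0062414902127982744, -0.077571493840045719, -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.72430852843777294, 0.60382926979718965, -0.16010239797419293)),
  `db6` = list(family = "daubechies",
    lo = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763, -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727, -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
    hi = c(-0.0010773010853084796, -0.0047772575109455108, 0.00055384220116149613, 0.03158203931748603, 0.027522865530305727, -0.097501605587323043, -0.12976686756726194, 0.22626469396543983, 0.31525035170919763, -0.75113390802109536, 0.49462389039845306, -0.11154074335010947)),
  `db7` = list(family = "daubechies",
    lo = c(0.077852054085009184, 0.39653931948191729, 0.72913209084623509, 0.46978228740519312, -0.14390600392856498, -0.22403618499387498, 0.071309219266830259, 0.080612609151083078, -0.038029936935014413, -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651, -0.0018016407040474908, 0.00035371379997452024),
    hi = c(0.00035371379997452024, 0.0018016407040474908, 0.00042957797292136651, -0.01255099855609984, -0.016574541630666881, 0.038029936935014413, 0.080612609151083078, -0.071309219266830259, -0.22403618499387498, 0.14390600392856498, 0.46978228740519312, -0.72913209084623509, 0.39653931948191729, -0.077852054085009184)),
  `db8` = list(family = "daubechies",
    lo = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976, 0.58535468365420673, -0.015829105256349306, -0.28401554296154691, 0.00047248457391328279, 0.12874742662047847, -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766, -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933, -0.00011747678412476953),
    hi = c(-0.00011747678412476953, -0.00067544940645056933, -0.00039174037337694705, 0.0048703529934515741, 0.0087460940474057766, -0.013981027917398282, -0.044088253930794755, 0.017369301001807547, 0.12874742662047847, -0.00047248457391328279, -0.28401554296154691, 0.015829105256349306, 0.58535468365420673, -0.67563073629728976, 0.31287159091429995, -0.054415842243104008)),
  `db9` = list(family = "daubechies",
    lo = c(0.038077947363878345, 0.24383467461259034, 0.60482312369011115, 0.65728807805130052, 0.13319738582500756, -0.29327378327917492, -0.096840783222976456, 0.14854074933810638, 0.03072568147933338, -0.067632829061329974, 0.00025094711483145197, 0.022361662123679096, -0.0047232047577513972, -0.0042815036824634303, 0.0018476468830562265, 0.00023038576352319597, -0.00025196318894271012, 3.9347320316271603e-05),
    hi = c(3.9347320316271603e-05, 0.00025196318894271012, 0.00023038576352319597, -0.0018476468830562265, -0.0042815036824634303, 0.0047232047577513972, 0.022361662123679096, -0.00025094711483145197, -0.067632829061329974, -0.03072568147933338, 0.14854074933810638, 0.096840783222976456, -0.29327378327917492, -0.13319738582500756, 0.65728807805130052, -0.60482312369011115, 0.24383467461259034, -0.038077947363878345)),
  `db10` = list(family = "daubechies",
    lo = c(0.026670057900555554, 0.1881768000776915, 0.52720118893172563, 0.68845903945360354, 0.28117234366057747, -0.24984642432731538, -0.19594627437737705, 0.12736934033579325, 0.093057364603572348, -0.071394147166397082, -0.029457536821875813, 0.033212674059341002, 0.0036065535669561697, -0.010733175483330575, 0.0013953517470529011, 0.0019924052951850561, -0.00068585669495971162, -0.00011646685512928545, 9.3588670320069592e-05, -1.3264202894521244e-05),
    hi = c(-1.3264202894521244e-05, -9.3588670320069592e-05, -0.00011646685512928545, 0.00068585669495971162, 0.0019924052951850561, -0.0013953517470529011, -0.010733175483330575, -0.0036065535669561697, 0.033212674059341002, 0.029457536821875813, -0.071394147166397082, -0.093057364603572348, 0.12736934033579325, 0.19594627437737705, -0.24984642432731538, -0.28117234366057747, 0.68845903945360354, -0.52720118893172563, 0.1881768000776915, -0.026670057900555554)),
  `db11` = list(family = "daubechies",
    lo = c(0.018694297761471083, 0.1440670211506245, 0.44989976435604534, 0.68568677491620056, 0.41196436894790744, -0.16227524502749036, -0.27423084681794696, 0.066043588196683198, 0.14981201246637849, -0.046479955116684187, -0.066438785695025204, 0.031335090219046076, 0.020840904360181062, -0.015364820906201599, -0.0033408588730144454, 0.0049284176560590413, -0.00030859285881514319, -0.00089302325066626461, 0.00024915252355282348, 5.4439074699368475e-05, -3.4634984186984996e-05, 4.4942742772365103e-06),
    hi = c(4.4942742772365103e-06, 3.4634984186984996e-05, 5.4439074699368475e-05, -0.00024915252355282348, -0.00089302325066626461, 0.00030859285881514319, 0.0049284176560590413, 0.0033408588730144454, -0.015364820906201599, -0.020840904360181062, 0.031335090219046076, 0.066438785695025204, -0.046479955116684187, -0.14981201246637849, 0.066043588196683198, 0.27423084681794696, -0.16227524502749036, -0.41196436894790744, 0.68568677491620056, -0.44989976435604534, 0.1440670211506245, -0.018694297761471083)),
  `db12` = list(family = "daubechies",
    lo = c(0.013112257957229518, 0.10956627282118515, 0.37735513521421266, 0.65719872257930712, 0.51588647842781565, -0.044763885653774628, -0.31617845375278553, -0.023779257256069726, 0.18247860592757967, 0.0053595696743521503, -0.096432120096507076, 0.010849130255822185, 0.041546277495084438, -0.01221864906974828, -0.012840825198300683, 0.0067114990087955096, 0.0022486072409952378, -0.0021795036186277603, 6.5451282125095959e-06, 0.00038865306282093143, -8.850410920820432e-05, -2.4241545757030785e-05, 1.2776952219379767e-05, -1.5290717580685109e-06),
    hi = c(-1.5290717580685109e-06, -1.2776952219379767e-05, -2.4241545757030785e-05, 8.850410920820432e-05, 0.00038865306282093143, -6.5451282125095959e-06, -0.0021795036186277603, -0.0022486072409952378, 0.0067114990087955096, 0.012840825198300683, -0.01221864906974828, -0.041546277495084438, 0.010849130255822185, 0.096432120096507076, 0.0053595696743521503, -0.18247860592757967, -0.023779257256069726, 0.31617845375278553, -0.044763885653774628, -0.51588647842781565, 0.65719872257930712, -0.37735513521421266, 0.10956627282118515, -0.013112257957229518)),
  `db13` = list(family = "daubechies",
    lo = c(0.0092021335389623673, 0.082861243872902779, 0.31199632216043804, 0.61105585115878769, 0.58888957043121892, 0.086985726179647241, -0.31497290771138864, -0.12457673075081525, 0.17947607942933985, 0.072948933656777168, -0.10580761818793433, -0.026488406475343694, 0.056139477100283428, 0.0023799722540590786, -0.02383142071032365, 0.0039239414487974161, 0.0072555894016175662, -0.0027619112346568622, -0.0013156739118922989, 0.00093232613086726335, 4.9251525126289464e-05, -0.00016512898855650549, 3.0678537579325496e-05, 1.0441930571408138e-05, -4.7004164793608683e-06, 5.2200350984548644e-07),
    hi = c(5.2200350984548644e-07, 4.7004164793608683e-06, 1.0441930571408138e-05, -3.0678537579325496e-05, -0.00016512898855650549, -4.9251525126289464e-05, 0.00093232613086726335, 0.0013156739118922989, -0.0027619112346568622, -0.0072555894016175662, 0.0039239414487974161, 0.02383142071032365, 0.0023799722540590786, -0.056139477100283428, -0.026488406475343694, 0.10580761818793433, 0.072948933656777168, -0.17947607942933985, -0.12457673075081525, 0.31497290771138864, 0.086985726179647241, -0.58888957043121892, 0.61105585115878769, -0.31199632216043804, 0.082861243872902779, -0.0092021335389623673)),
  `db14` = list(family = "daubechies",
    lo = c(0.0064611534600879476, 0.062364758849398898, 0.25485026779262138, 0.55430561794089384, 0.63118784910485681, 0.21867068775890652, -0.27168855227874805, -0.21803352999327605, 0.1383952138648066, 0.1399890165844607, -0.086748411568169689, -0.071548955504046136, 0.055237126259216042, 0.026981408307912916, -0.030185351540390634, -0.0056150495303569593, 0.012789493266333409, -0.00074621898926838497, -0.0038496388680221874, 0.0010616910856067619, 0.00070802115423552786, -0.0003868319473129545, -4.1777245770372596e-05, 6.8755042526975093e-05, -1.0337209184570774e-05, -4.3897049017813942e-06, 1.7249946753678127e-06, -1.7871399683113592e-07),
    hi = c(-1.7871399683113592e-07, -1.7249946753678127e-06, -4.3897049017813942e-06, 1.0337209184570774e-05, 6.8755042526975093e-05, 4.1777245770372596e-05, -0.0003868319473129545, -0.00070802115423552786, 0.0010616910856067619, 0.0038496388680221874, -0.00074621898926838497, -0.012789493266333409, -0.0056150495303569593, 0.030185351540390634, 0.026981408307912916, -0.055237126259216042, -0.071548955504046136, 0.086748411568169689, 0.1399890165844607, -0.1383952138648066, -0.21803352999327605, 0.27168855227874805, 0.21867068775890652, -0.63118784910485681, 0.55430561794089384, -0.25485026779262138, 0.062364758849398898, -0.0064611534600879476)),
  `db15` = list(family = "daubechies",
    lo = c(0.0045385373615788992, 0.046743394892766271, 0.20602386398699574, 0.4926317717081396, 0.64581314035742432, 0.33900253545473152, -0.19320413960914543, -0.28888259656696563, 0.065282952848772821, 0.19014671400712299, -0.039666176555790945, -0.11112093603723169, 0.033877143923507685, 0.054780550584507613, -0.025767007328439964, -0.020810050169693083, 0.015083918027835902, 0.0051010003604075429, -0.0064877345603157454, -0.00024175649076162427, 0.0019433239803822114, -0.00037348235413761698, -0.00035956524436246879, 0.00015589648992059973, 2.5792699155318936e-05, -2.8133296266047814e-05, 3.36298718173758e-06, 1.8112704079405772e-06, -6.3168823258816645e-07, 6.133359913305752e-08),
    hi = c(6.133359913305752e-08, 6.3168823258816645e-07, 1.8112704079405772e-06, -3.36298718173758e-06, -2.8133296266047814e-05, -2.5792699155318936e-05, 0.00015589648992059973, 0.00035956524436246879, -0.00037348235413761698, -0.0019433239803822114, -0.00024175649076162427, 0.0064877345603157454, 0.0051010003604075429, -0.015083918027835902, -0.020810050169693083, 0.025767007328439964, 0.054780550584507613, -0.033877143923507685, -0.11112093603723169, 0.039666176555790945, 0.19014671400712299, -0.065282952848772821, -0.28888259656696563, 0.19320413960914543, 0.33900253545473152, -0.64581314035742432, 0.4926317717081396, -0.20602386398699574, 0.046743394892766271, -0.0045385373615788992)),
  `db16` = list(family = "daubechies",
    lo = c(0.0031892209253477381, 0.034907714323673344, 0.16506428348885313, 0.4303127228460038, 0.63735633208378895, 0.44029025688635692, -0.089751089402489645, -0.32706331052791771, -0.027918208133028276, 0.2111906939471043, 0.027340263752716042, -0.1323883055638104, -0.006239722752474872, 0.075924236044276311, -0.0075889743688577378, -0.036888397691730142, 0.01029765964095597, 0.013993768859828731, -0.0069900145634139163, -0.0036442796214983899, 0.003128023381206269, 0.00040789698084971285, -0.00094102174935956756, 0.00011424152003872239, 0.00017478724522533817, -6.103596621410936e-05, -1.3945668988208893e-05, 1.1336608661276258e-05, -1.0435713423116066e-06, -7.3636567854512051e-07, 2.3087840868575457e-07, -2.1093396301007431e-08),
    hi = c(-2.1093396301007431e-08, -2.3087840868575457e-07, -7.3636567854512051e-07, 1.0435713423116066e-06, 1.1336608661276258e-05, 1.3945668988208893e-05, -6.103596621410936e-05, -0.00017478724522533817, 0.00011424152003872239, 0.00094102174935956756, 0.00040789698084971285, -0.003128023381206269, -0.0036442796214983899, 0.0069900145634139163, 0.013993768859828731, -0.01029765964095597, -0.036888397691730142, 0.0075889743688577378, 0.075924236044276311, 0.006239722752474872, -0.1323883055638104, -0.027340263752716042, 0.2111906939471043, 0.027918208133028276, -0.32706331052791771, 0.089751089402489645, 0.44029025688635692, -0.63735633208378895, 0.4303127228460038, -0.16506428348885313, 0.034907714323673344, -0.0031892209253477381)),
  `db17` = list(family = "daubechies",
    lo = c(0.0022418070010373128, 0.025985393703606044, 0.1312149033078244, 0.37035072415264114, 0.61099661568462282, 0.5183157640569378, 0.027314970403293636, -0.32832074836396175, -0.12659975221588271, 0.19731058956501099, 0.10113548917747027, -0.1268156917782863, -0.05709141963167693, 0.081105986654160883, 0.022312336178103798, -0.046922438389269738, -0.0032709555358192938, 0.022733676583946271, -0.0030429899813546372, -0.0086029215203228555, 0.0029679966915260947, 0.0023012052421535457, -0.0014368453048029762, -0.00032813251940983797, 0.00043946542776864369, -2.5610109566548458e-05, -8.2048032024533915e-05, 2.3186813798745952e-05, 6.9906009850767515e-06, -4.5059424772229884e-06, 3.0165496099945573e-07, 2.9577009333168569e-07, -8.4239484460026796e-08, 7.2674929685616085e-09),
    hi = c(7.2674929685616085e-09, 8.4239484460026796e-08, 2.9577009333168569e-07, -3.0165496099945573e-07, -4.5059424772229884e-06, -6.9906009850767515e-06, 2.3186813798745952e-05, 8.2048032024533915e-05, -2.5610109566548458e-05, -0.00043946542776864369, -0.00032813251940983797, 0.0014368453048029762, 0.0023012052421535457, -0.0029679966915260947, -0.0086029215203228555, 0.0030429899813546372, 0.022733676583946271, 0.0032709555358192938, -0.046922438389269738, -0.022312336178103798, 0.081105986654160883, 0.05709141963167693, -0.1268156917782863, -0.10113548917747027, 0.19731058956501099, 0.12659975221588271, -0.32832074836396175, -0.027314970403293636, 0.5183157640569378, -0.61099661568462282, 0.37035072415264114, -0.1312149033078244, 0.025985393703606044, -0.0022418070010373128)),
  `db18` = list(family = "daubechies",
    lo = c(0.0015763102184407605, 0.019288531724146376, 0.10358846582242359, 0.31467894133703173, 0.57182680776660721, 0.57180165488865131, 0.14722311196992816, -0.29365404073655876, -0.21648093400514298, 0.14953397556537779, 0.16708131276325741, -0.092331884150846283, -0.10675224665982849, 0.064887216211905449, 0.057051247738536884, -0.044526141902982326, -0.023733210395860002, 0.026670705926470591, 0.0062621679543057073, -0.013051480946612001, 0.00011863003385811746, 0.0049433436054667377, -0.0011187326669924971, -0.0013405962983361066, 0.00062846568296514574, 0.0002135815619103407, -0.00019864855231174796, -1.5359171235347246e-07, 3.7412378807400385e-05, -8.5206025374466959e-06, -3.332634478885822e-06, 1.7687129836276155e-06, -7.6916326898851766e-08, -1.1760987670282317e-07, 3.0688358630451749e-08, -2.5079344549485983e-09),
    hi = c(-2.5079344549485983e-09, -3.0688358630451749e-08, -1.1760987670282317e-07, 7.6916326898851766e-08, 1.7687129836276155e-06, 3.332634478885822e-06, -8.5206025374466959e-06, -3.7412378807400385e-05, -1.5359171235347246e-07, 0.00019864855231174796, 0.0002135815619103407, -0.00062846568296514574, -0.0013405962983361066, 0.0011187326669924971, 0.0049433436054667377, -0.00011863003385811746, -0.013051480946612001, -0.0062621679543057073, 0.026670705926470591, 0.023733210395860002, -0.044526141902982326, -0.057051247738536884, 0.064887216211905449, 0.10675224665982849, -0.092331884150846283, -0.16708131276325741, 0.14953397556537779, 0.21648093400514298, -0.29365404073655876, -0.14722311196992816, 0.57180165488865131, -0.57182680776660721, 0.31467894133703173, -0.10358846582242359, 0.019288531724146376, -0.0015763102184407605)),
  `db19` = list(family = "daubechies",
    lo = c(0.0011086697631817106, 0.014281098450764397, 0.081278113265459556, 0.26438843174089677, 0.52443637746465488, 0.6017045491275379, 0.26089495265103885, -0.22809139421548263, -0.28583863175582624, 0.074652269708103264, 0.21234974330627848, -0.033518541902302877, -0.14278569503873659, 0.027584350625628667, 0.086906755555812232, -0.026501236250123041, -0.04567422627723091, 0.021623767409585049, 0.019375549889176127, -0.013988388678535142, -0.0058669222810121746, 0.0070407473671052429, 0.00076895435925754838, -0.0026875518007015821, 0.00034180865345859575, 0.00073580252050543522, -0.000260676135678628, -0.00012460079173415878, 8.7112704672199229e-05, 5.1059504870738862e-06, -1.6640176297154945e-05, 3.0109643162965265e-06, 1.531931476691193e-06, -6.8627556577691427e-07, 1.4470882987978445e-08, 4.6369377757826045e-08, -1.1164020670358259e-08, 8.6668488389976189e-10),
    hi = c(8.6668488389976189e-10, 1.1164020670358259e-08, 4.6369377757826045e-08, -1.4470882987978445e-08, -6.8627556577691427e-07, -1.531931476691193e-06, 3.0109643162965265e-06, 1.6640176297154945e-05, 5.1059504870738862e-06, -8.7112704672199229e-05, -0.00012460079173415878, 0.000260676135678628, 0.00073580252050543522, -0.00034180865345859575, -0.0026875518007015821, -0.00076895435925754838, 0.0070407473671052429, 0.0058669222810121746, -0.013988388678535142, -0.019375549889176127, 0.021623767409585049, 0.04567422627723091, -0.026501236250123041, -0.086906755555812232, 0.027584350625628667, 0.14278569503873659, -0.033518541902302877, -0.21234974330627848, 0.074652269708103264, 0.28583863175582624, -0.22809139421548263, -0.26089495265103885, 0.6017045491275379, -0.52443637746465488, 0.26438843174089677, -0.081278113265459556, 0.014281098450764397, -0.0011086697631817106)),
  `db20` = list(family = "daubechies",
    lo = c(0.00077995361366684629, 0.010549394624950399, 0.063423780459081522, 0.21994211355139703, 0.47269618531090168, 0.61049323893859386, 0.36150229873933104, -0.13921208801148388, -0.32678680043403496, -0.016727088309077008, 0.22829105081991632, 0.039850246457771202, -0.15545875070726795, -0.024716827338613585, 0.10229171917444256, 0.0056322468573074356, -0.061722899624680458, 0.0058746818118118266, 0.03229429953076958, -0.0087893249239015606, -0.01381052613715192, 0.006721627302259457, 0.0044205423870457908, -0.0035814942596096226, -0.00083156217282255693, 0.0013925596193231364, -5.3497598439976948e-05, -0.00038510474869921763, 0.00010153288973670291, 6.7742808283777301e-05, -3.7105861833947128e-05, -4.3761438621839971e-06, 7.2412482876736205e-06, -1.0119940100188862e-06, -6.8470795970005574e-07, 2.6339242262700013e-07, 2.0143220235505126e-10, -1.814843248299696e-08, 4.0561270555518328e-09, -2.9988364896193194e-10),
    hi = c(-2.9988364896193194e-10, -4.0561270555518328e-09, -1.814843248299696e-08, -2.0143220235505126e-10, 2.6339242262700013e-07, 6.8470795970005574e-07, -1.0119940100188862e-06, -7.2412482876736205e-06, -4.3761438621839971e-06, 3.7105861833947128e-05, 6.7742808283777301e-05, -0.00010153288973670291, -0.00038510474869921763, 5.3497598439976948e-05, 0.0013925596193231364, 0.00083156217282255693, -0.0035814942596096226, -0.0044205423870457908, 0.006721627302259457, 0.01381052613715192, -0.0087893249239015606, -0.03229429953076958, 0.0058746818118118266, 0.061722899624680458, 0.0056322468573074356, -0.10229171917444256, -0.024716827338613585, 0.15545875070726795, 0.039850246457771202, -0.22829105081991632, -0.016727088309077008, 0.32678680043403496, -0.13921208801148388, -0.36150229873933104, 0.61049323893859386, -0.47269618531090168, 0.21994211355139703, -0.063423780459081522, 0.010549394624950399, -0.00077995361366684629)),
  `sym3` = list(family = "symlets",
    lo = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132, -0.13501102001039084, -0.085441273882241486, 0.035226291882100656),
    hi = c(0.035226291882100656, 0.085441273882241486, -0.13501102001039084, -0.45987750211933132, 0.80689150931333875, -0.33267055295095688)),
  `sym4` = list(family = "symlets",
    lo = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736, 0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
    hi = c(-0.075765714789273325, 0.02963552764599851, 0.49761866763201545, -0.80373875180591614, 0.29785779560527736, 0.099219543576847216, -0.012603967262037833, -0.032223100604042702)),
  `sym5` = list(family = "symlets",
    lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.016602105764522319, 0.63397896345821192, 0.72340769040242059, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
    hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936, 0.72340769040242059, -0.63397896345821192, 0.016602105764522319, 0.17532808990845047, -0.021101834024758855, -0.019538882735286728)),
  `sym6` = list(family = "symlets",
    lo = c(-0.007800708325034148, 0.0017677118642428036, 0.044724901770665779, -0.021060292512300564, -0.072637522786462516, 0.3379294217276218, 0.787641141030194, 0.49105594192674662, -0.048311742585632998, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
    hi = c(0.015404109327027373, -0.0034907120842174702, -0.11799011114819057, 0.048311742585632998, 0.49105594192674662, -0.787641141030194, 0.3379294217276218, 0.072637522786462516, -0.021060292512300564, -0.044724901770665779, 0.0017677118642428036, 0.007800708325034148)),
  `sym7` = list(family = "symlets",
    lo = c(0.010268176708511255, 0.0040102448715336634, -0.10780823770381774, -0.14004724044296152, 0.28862963175151463, 0.76776431700316405, 0.5361019170917628, 0.017441255086855827, -0.049552834937127255, 0.067892693501372697, 0.03051551316596357, -0.01263630340325193, -0.0010473848886829163, 0.0026818145682578781),
    hi = c(0.0026818145682578781, 0.0010473848886829163, -0.01263630340325193, -0.03051551316596357, 0.067892693501372697, 0.049552834937127255, 0.017441255086855827, -0.5361019170917628, 0.76776431700316405, -0.28862963175151463, -0.14004724044296152, 0.10780823770381774, 0.0040102448715336634, -0.010268176708511255)),
  `sym8` = list(family = "symlets",
    lo = c(0.0018899503327594609, -0.0003029205147213668, -0.014952258337048231, 0.0038087520138906151, 0.049137179673607506, -0.027219029917056003, -0.051945838107709037, 0.3644418948353314, 0.77718575170052351, 0.48135965125837221, -0.061273359067658524, -0.14329423835080971, 0.0076074873249176054, 0.031695087811492981, -0.00054213233179114812, -0.0033824159510061256),
    hi = c(-0.0033824159510061256, 0.00054213233179114812, 0.031695087811492981, -0.0076074873249176054, -0.14329423835080971, 0.061273359067658524, 0.48135965125837221, -0.77718575170052351, 0.3644418948353314, 0.051945838107709037, -0.027219029917056003, -0.049137179673607506, 0.0038087520138906151, 0.014952258337048231, -0.0003029205147213668, -0.0018899503327594609)),
  `sym10` = list(family = "symlets",
    lo = c(-0.00045932942100465878, 5.7036083618494284e-05, 0.0045931735853118284, -0.00080435893201654491, -0.02035493981231129, 0.0057649120335819086, 0.049994972077376687, -0.0319900568824278, -0.035536740473817552, 0.38382676106708546, 0.7695100370211071, 0.47169066693843925, -0.070880535783243853, -0.15949427888491757, 0.011609893903711381, 0.045927239231092203, -0.0014653825813050513, -0.0086412992770224222, 9.5632670722894754e-05, 0.00077015980911449011),
    hi = c(0.00077015980911449011, -9.5632670722894754e-05, -0.0086412992770224222, 0.0014653825813050513, 0.045927239231092203, -0.011609893903711381, -0.15949427888491757, 0.070880535783243853, 0.47169066693843925, -0.7695100370211071, 0.38382676106708546, 0.035536740473817552, -0.0319900568824278, -0.049994972077376687, 0.0057649120335819086, 0.02035493981231129, -0.00080435893201654491, -0.0045931735853118284, 5.7036083618494284e-05, 0.00045932942100465878)),
  `sym20` = list(family = "symlets",
    lo = c(-6.3291290447763946e-07, -3.2567026420174407e-07, 1.22872527779612e-05, 4.5254222091516362e-06, -0.00011739133516291466, -2.6615550335516086e-05, 0.00074761085978205719, 0.00012544091723067259, -0.0034716478028440734, -0.0006111263857992088, 0.012157040948785737, 0.0019385970672402002, -0.035373336756604236, -0.0068437019650692274, 0.088919668028199561, 0.036250951653933078, -0.16057829841525254, -0.051088342921067398, 0.47199147510148703, 0.75116272842273002, 0.40583144434845059, -0.029819368880333728, -0.078994344928398158, 0.025579349509413946, 0.0081232283560096815, -0.031629437144957966, -0.0033138573836233591, 0.017004049023390339, 0.0014230873594621453, -0.0066065857990888609, -0.0003052628317957281, 0.0020889947081901982, 7.2159911880740349e-05, -0.00049473109156726548, -1.928412300645204e-05, 7.992967835772481e-05, 3.0256660627369661e-06, -7.919361411976999e-06, -1.9015675890554106e-07, 3.695537474835221e-07),
    hi = c(3.695537474835221e-07, 1.9015675890554106e-07, -7.919361411976999e-06, -3.0256660627369661e-06, 7.992967835772481e-05, 1.928412300645204e-05, -0.00049473109156726548, -7.2159911880740349e-05, 0.0020889947081901982, 0.0003052628317957281, -0.0066065857990888609, -0.0014230873594621453, 0.017004049023390339, 0.0033138573836233591, -0.031629437144957966, -0.0081232283560096815, 0.025579349509413946, 0.078994344928398158, -0.029819368880333728, -0.40583144434845059, 0.75116272842273002, -0.47199147510148703, -0.051088342921067398, 0.16057829841525254, 0.036250951653933078, -0.088919668028199561, -0.0068437019650692274, 0.035373336756604236, 0.0019385970672402002, -0.012157040948785737, -0.0006111263857992088, 0.0034716478028440734, 0.00012544091723067259, -0.00074761085978205719, -2.6615550335516086e-05, 0.00011739133516291466, 4.5254222091516362e-06, -1.22872527779612e-05, -3.2567026420174407e-07, 6.3291290447763946e-07)),
  `coif3` = list(family = "coiflets",
    lo = c(-0.0037935128643808019, 0.0077825964256727463, 0.023452696142077168, -0.065771911281469364, -0.061123390002972552, 0.40517690240911824, 0.79377722262608719, 0.42848347637737, -0.071799821619154838, -0.082301927106299827, 0.034555027573297738, 0.015880544863669452, -0.0090079761367306242, -0.0025745176881367972, 0.0011175187708306303, 0.00046621695982040288, -7.0983302506379004e-05, -3.4599773197272781e-05),
    hi = c(-3.4599773197272781e-05, 7.0983302506379004e-05, 0.00046621695982040288, -0.0011175187708306303, -0.0025745176881367972, 0.0090079761367306242, 0.015880544863669452, -0.034555027573297738, -0.082301927106299827, 0.071799821619154838, 0.42848347637737, -0.79377722262608719, 0.40517690240911824, 0.061123390002972552, -0.065771911281469364, -0.023452696142077168, 0.0077825964256727463, 0.0037935128643808019)),
  `coif4` = list(family = "coiflets",
    lo = c(0.00089231390253700297, -0.001629492425226786, -0.0073461679362680507, 0.016068947131575029, 0.02668230466960483, -0.081266710249193727, -0.056077319603569258, 0.41530842700068227, 0.78223893442428261, 0.43438603311435653, -0.066627472366817167, -0.096220424535952642, 0.039334422605589149, 0.025082253337949612, -0.015211728187697211, -0.0056582838001308835, 0.0037514346971460866, 0.0012665610789256603, -0.00058902022463321654, -0.00025997433712225682, 6.2338854312787192e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05, -6.2338854312787192e-05, -0.00025997433712225682, 0.00058902022463321654, 0.0012665610789256603, -0.0037514346971460866, -0.0056582838001308835, 0.015211728187697211, 0.025082253337949612, -0.039334422605589149, -0.096220424535952642, 0.066627472366817167, 0.43438603311435653, -0.78223893442428261, 0.41530842700068227, 0.056077319603569258, -0.081266710249193727, -0.02668230466960483, 0.016068947131575029, 0.0073461679362680507, -0.001629492425226786, -0.00089231390253700297)),
  `coif5` = list(family = "coiflets",
    lo = c(-0.000212081862067494, 0.00035857774116175768, 0.0021782943778456947, -0.0041593126275786402, -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.091921588060086087, -0.052046670253554764, 0.42157126673075435, 0.77429362286032744, 0.43798230665916338, -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355, -0.019758391600965465, -0.0091595073386761625, 0.0067615202206204169, 0.0024315754425382886, -0.0016616273039298788, -0.00063755892612588115, 0.00030185794166824478, 0.00014035632812373243, -4.1219861924265501e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06, -1.6237995172048338e-07, -9.6040101127678941e-08),
    hi = c(-9.6040101127678941e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06, -2.1270221672515614e-05, 4.1219861924265501e-05, 0.00014035632812373243, -0.00030185794166824478, -0.00063755892612588115, 0.0016616273039298788, 0.0024315754425382886, -0.0067615202206204169, -0.0091595073386761625, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834, -0.10556315130733723, 0.06203775157498196, 0.43798230665916338, -0.77429362286032744, 0.42157126673075435, 0.052046670253554764, -0.091921588060086087, -0.028169744270532353, 0.023408322118927783, 0.010131584846900276, -0.0041593126275786402, -0.0021782943778456947, 0.00035857774116175768, 0.000212081862067494)),
  `bior1.1` = list(family = "biorthogonal",
    lo = c(0.70710678118654757, 0.70710678118654757),
    hi = c(0.70710678118654757, -0.70710678118654757)),
  `bior2.2` = list(family = "biorthogonal",
    lo = c(0, -0.17677669529663689, 0.35355339059327379, 1.0606601717798212, 0.35355339059327379, -0.17677669529663689),
    hi = c(0, -0.35355339059327379, 0.70710678118654757, -0.35355339059327379, 0, -0)),
  `bior3.3` = list(family = "biorthogonal",
    lo = c(0.066291260736238825, -0.19887378220871649, -0.15467960838455727, 0.99436891104358249, 0.99436891104358249, -0.15467960838455727, -0.19887378220871649, 0.066291260736238825),
    hi = c(-0, 0, -0.17677669529663689, 0.5303300858899106, -0.5303300858899106, 0.17677669529663689, -0, 0)),
  `bior4.4` = list(family = "biorthogonal",
    lo = c(0, 0.03782845550726404, -0.023849465019556843, -0.11062440441843718, 0.37740285561283066, 0.85269867900889385, 0.37740285561283066, -0.11062440441843718, -0.023849465019556843, 0.03782845550726404),
    hi = c(0, 0.064538882628697058, -0.040689417609164058, -0.41809227322161724, 0.7884856164055829, -0.41809227322161724, -0.040689417609164058, 0.064538882628697058, 0, -0))
)
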