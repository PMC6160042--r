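# Frozen reference values computed with PyWavelets 1.9.0,
# wavelet 'sym10', mode 'periodization'.
pywt_x16 <- c(0.30471707975443135, -1.0399841062404955, 0.75045119580645725, 0.94056471639121386, -1.9510351886538364, -1.3021795068623181, 0.12784040316728537, -0.31624259234358221, -0.016801157504288795, -0.85304392757358005, 0.87939797486282856, 0.77779193542894831, 0.066030697561216045, 1.1272412069680329, 0.4675093422520456, -0.85929246288323824)
pywt_flat <- c(-0.22425859746721988, 0.66165555586181768, 0.48406099623447751, -1.4769778036633712, -0.21011538981942884, 1.3498434537786097, 0.42531619857648995, -0.49822168388104282, -1.0523508133647352, -0.54889947446467491, 1.6406157240955117, -1.1844775166164709, -0.15300545295324569, -0.86373353039596301, 0.99147837997315191, -0.3522085880497603)
pywt_X8 <- matrix(c(0.36875078408249884, -0.9588826008289989, 0.87845030130727253, -0.049925910986252896, -0.18486236354526056, -0.68092954440394138, 1.2225413386740303, -0.15452948206880215, -0.42832782216310722, -0.35213355048822959, 0.53230918555334872, 0.36544406436407834, 0.4127326115959884, 0.43082100300788273, 2.1416476008704612, -0.40641501638461558, -0.51224272907153734, -0.81377272824787772, 0.61597942257549565, 1.1289722927208916, -0.11394745765487507, -0.84015647696252804, -0.82448121569123956, 0.65059278782470109, 0.74325417120344228, 0.54315426830519498, -0.6655097072886943, 0.23216132306671977, 0.11668580914072822, 0.21868859672901295, 0.87142877794818985, 0.22359554877468227, 0.67891356307189488, 0.067579069488891461, 0.28911939868998415, 0.63128822583854038, -1.4571558198556664, -0.31967121635730134, -0.47037265429279551, -0.63887784824334193, -0.27514225122668373, 1.4949413112343959, -0.86583111569324323, 0.96827835459148082, -1.6828697716158048, -0.33488502998577485, 0.16275306510500559, 0.58622233135927815, 0.71122657979285497, 0.79334723519992523, -0.34872507224843757, -0.46235179266456716, 0.85797588125715385, -0.19130432488161489, -1.2756863233379219, -1.1332872140034806, -0.91945228600161133, 0.49716074405376404, 0.14242573607056525, 0.69048535406776823, -0.42725264633653426, 0.15853969107671423, 0.62559039396733673, -0.3093465397202384), nrow=8, byrow=TRUE)
pywt_cA <- matrix(c(-0.63411708960965474, 0.87469329671167417, 0.68712611459208706, 0.39374627649117272, 0.1484027824975454, 0.39067661015237842, -0.45276237801440972, 0.63243621634593805, 1.108406969681162, -0.28377612104098643, -1.146045636988716, -0.35007916369899578, 0.39448359485271473, 0.015904651820112907, 0.22345323242886772, -0.52518520104129307), nrow=4, byrow=TRUE)
pywt_cH <- matrix(c(0.0045604476281764089, 0.24223093235560283, 0.99487434345229508, -0.63135246038592807, 0.54089234541163911, -0.97859501287733941, 1.7144568445996986, 0.60901241636981374, -0.0033917904851632056, -0.1334686616017095, 0.43148070753315493, 0.7672780905854053, -0.04347601273039494, -0.17845548961200056, -0.0048409399114469022, 0.6825842896701001), nrow=4, byrow=TRUE)
pywt_cV <- matrix(c(0.32658133933907973, -1.1211245182289056, 0.29674533370245648, -1.6159180903480808, -0.25428117290289859, 0.28593800249621637, 0.83784615225601544, -0.44392242757421829, 0.24601069826488337, 1.7316583762354079, 0.8858535641163986, 0.18796579531891838, -0.090527234570864062, 0.10511586377190375, 0.028055736369684833, -0.84855864794923808), nrow=4, byrow=TRUE)
pywt_cD <- matrix(c(0.58226325641686005, 0.67596935315989204, -0.040525491586382884, 0.23776422453538523, -0.53400274784201063, 0.31755465586832005, -0.26234168219231324, -1.2102914549273318, 0.89314116355464912, 0.98231336716922002, -0.51711604466047267, 0.25327802896700263, 1.5396314558730799, 0.074489959191447408, 1.9530501728992766, -0.98034628380065525), nrow=4, byrow=TRUE)
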