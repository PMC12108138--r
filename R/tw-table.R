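# Tracy-Widom (beta = 1) distribution table.
#
# Cumulative distribution F1(s) of the Tracy-Widom law for the Gaussian
# orthogonal ensemble, tabulated on a regular grid of the standardized
# largest-eigenvalue statistic s.  Computed once, offline, from the
# Painleve II representation with the Hastings-McLeod boundary condition
# (q ~ Ai(s) as s -> +inf), i.e. F2(s) = exp(-int_s^inf (x-s) q(x)^2 dx)
# and F1(s) = sqrt(F2(s)) * exp(-(1/2) int_s^inf q(x) dx), integrated at
# rtol 1e-11.  Spot checks against the standard upper-tail thresholds:
# F1^-1(0.95) = 0.9793, F1^-1(0.99) = 2.0234, F1^-1(0.999) = 3.2723,
# mean -1.2065, sd 1.2679.

.tw1_s <- c(-6.16, -6.14, -6.12, -6.1, -6.08, -6.06, -6.04, -6.02, -6, -5.98, -5.96, -5.94, -5.92, -5.9, -5.88, -5.86, -5.84, -5.82, -5.8, -5.78, -5.76, -5.74, -5.72, -5.7, -5.68, -5.66, -5.64, -5.62, -5.6, -5.58, -5.56, -5.54, -5.52, -5.5, -5.48, -5.46, -5.44, -5.42, -5.4, -5.38, -5.36, -5.34, -5.32, -5.3, -5.28, -5.26, -5.24, -5.22, -5.2, -5.18, -5.16, -5.14, -5.12, -5.1, -5.08, -5.06, -5.04, -5.02, -5, -4.98, -4.96, -4.94, -4.92, -4.9, -4.88, -4.86, -4.84, -4.82, -4.8, -4.78, -4.76, -4.74, -4.72, -4.7, -4.68, -4.66, -4.64, -4.62, -4.6, -4.58, -4.56, -4.54, -4.52, -4.5, -4.48, -4.46, -4.44, -4.42, -4.4, -4.38, -4.36, -4.34, -4.32, -4.3, -4.28, -4.26, -4.24, -4.22, -4.2, -4.18, -4.16, -4.14, -4.12, -4.1, -4.08, -4.06, -4.04, -4.02, -4, -3.98, -3.96, -3.94, -3.92, -3.9, -3.88, -3.86, -3.84, -3.82, -3.8, -3.78, -3.76, -3.74, -3.72, -3.7, -3.68, -3.66, -3.64, -3.62, -3.6, -3.58, -3.56, -3.54, -3.52, -3.5, -3.48, -3.46, -3.44, -3.42, -3.4, -3.38, -3.36, -3.34, -3.32, -3.3, -3.28, -3.26, -3.24, -3.22, -3.2, -3.18, -3.16, -3.14, -3.12, -3.1, -3.08, -3.06, -3.04, -3.02, -3, -2.98, -2.96, -2.94, -2.92, -2.9, -2.88, -2.86, -2.84, -2.82, -2.8, -2.78, -2.76, -2.74, -2.72, -2.7, -2.68, -2.66, -2.64, -2.62, -2.6, -2.58, -2.56, -2.54, -2.52, -2.5, -2.48, -2.46, -2.44, -2.42, -2.4, -2.38, -2.36, -2.34, -2.32, -2.3, -2.28, -2.26, -2.24, -2.22, -2.2, -2.18, -2.16, -2.14, -2.12, -2.1, -2.08, -2.06, -2.04, -2.02, -2, -1.98, -1.96, -1.94, -1.92, -1.9, -1.88, -1.86, -1.84, -1.82, -1.8, -1.78, -1.76, -1.74, -1.72, -1.7, -1.68, -1.66, -1.64, -1.62, -1.6, -1.58, -1.56, -1.54, -1.52, -1.5, -1.48, -1.46, -1.44, -1.42, -1.4, -1.38, -1.36, -1.34, -1.32, -1.3, -1.28, -1.26, -1.24, -1.22, -1.2, -1.18, -1.16, -1.14, -1.12, -1.1, -1.08, -1.06, -1.04, -1.02, -1, -0.98, -0.96, -0.94, -0.92, -0.9, -0.88, -0.86, -0.84, -0.82, -0.8, -0.78, -0.76, -0.74, -0.72, -0.7, -0.68, -0.66, -0.64, -0.62, -0.6, -0.58, -0.56, -0.54, -0.52, -0.5, -0.48, -0.46, -0.44, -0.42, -0.4, -0.38, -0.36, -0.34, -0.32, -0.3, -0.28, -0.26, -0.24, -0.22, -0.2, -0.18, -0.16, -0.14, -0.12, -0.1, -0.08, -0.06, -0.04, -0.02, -2.13163e-13, 0.02, 0.04, 0.06, 0.08, 0.1, 0.12, 0.14, 0.16, 0.18, 0.2, 0.22, 0.24, 0.26, 0.28, 0.3, 0.32, 0.34, 0.36, 0.38, 0.4, 0.42, 0.44, 0.46, 0.48, 0.5, 0.52, 0.54, 0.56, 0.58, 0.6, 0.62, 0.64, 0.66, 0.68, 0.7, 0.72, 0.74, 0.76, 0.78, 0.8, 0.82, 0.84, 0.86, 0.88, 0.9, 0.92, 0.94, 0.96, 0.98, 1, 1.02, 1.04, 1.06, 1.08, 1.1, 1.12, 1.14, 1.16, 1.18, 1.2, 1.22, 1.24, 1.26, 1.28, 1.3, 1.32, 1.34, 1.36, 1.38, 1.4, 1.42, 1.44, 1.46, 1.48, 1.5, 1.52, 1.54, 1.56, 1.58, 1.6, 1.62, 1.64, 1.66, 1.68, 1.7, 1.72, 1.74, 1.76, 1.78, 1.8, 1.82, 1.84, 1.86, 1.88, 1.9, 1.92, 1.94, 1.96, 1.98, 2, 2.02, 2.04, 2.06, 2.08, 2.1, 2.12, 2.14, 2.16, 2.18, 2.2, 2.22, 2.24, 2.26, 2.28, 2.3, 2.32, 2.34, 2.36, 2.38, 2.4, 2.42, 2.44, 2.46, 2.48, 2.5, 2.52, 2.54, 2.56, 2.58, 2.6, 2.62, 2.64, 2.66, 2.68, 2.7, 2.72, 2.74, 2.76, 2.78, 2.8, 2.82, 2.84, 2.86, 2.88, 2.9, 2.92, 2.94, 2.96, 2.98, 3, 3.02, 3.04, 3.06, 3.08, 3.1, 3.12, 3.14, 3.16, 3.18, 3.2, 3.22, 3.24, 3.26, 3.28, 3.3, 3.32, 3.34, 3.36, 3.38, 3.4, 3.42, 3.44, 3.46, 3.48, 3.5, 3.52, 3.54, 3.56, 3.58, 3.6, 3.62, 3.64, 3.66, 3.68, 3.7, 3.72, 3.74, 3.76, 3.78, 3.8, 3.82, 3.84, 3.86, 3.88, 3.9, 3.92, 3.94, 3.96, 3.98, 4, 4.02, 4.04, 4.06, 4.08, 4.1, 4.12, 4.14, 4.16, 4.18, 4.2, 4.22, 4.24, 4.26, 4.28, 4.3, 4.32, 4.34, 4.36, 4.38, 4.4, 4.42, 4.44, 4.46, 4.48, 4.5, 4.52, 4.54, 4.56, 4.58, 4.6, 4.62, 4.64, 4.66, 4.68, 4.7, 4.72, 4.74, 4.76, 4.78, 4.8, 4.82, 4.84, 4.86, 4.88, 4.9, 4.92, 4.94, 4.96, 4.98, 5, 5.02, 5.04, 5.06, 5.08, 5.1, 5.12, 5.14, 5.16, 5.18, 5.2, 5.22, 5.24, 5.26, 5.28, 5.3, 5.32, 5.34, 5.36, 5.38, 5.4, 5.42, 5.44, 5.46, 5.48, 5.5, 5.52, 5.54, 5.56, 5.58, 5.6, 5.62, 5.64, 5.66, 5.68, 5.7, 5.72, 5.74, 5.76, 5.78, 5.8, 5.82, 5.84, 5.86, 5.88, 5.9, 5.92, 5.94, 5.96, 5.98, 6)

.tw1_cdf <- c(2.678884252e-08, 1.097898771e-07, 2.060419695e-07, 3.170872708e-07, 4.446211056e-07, 5.905054587e-07, 7.567835095e-07, 9.456952841e-07, 1.159694496e-06, 1.401466653e-06, 1.673948511e-06, 1.980348952e-06, 2.324171382e-06, 2.709237733e-06, 3.139714166e-06, 3.620138573e-06, 4.155449981e-06, 4.751019959e-06, 5.412686152e-06, 6.14678803e-06, 6.960205001e-06, 7.860396978e-06, 8.855447547e-06, 9.954109853e-06, 1.116585534e-05, 1.250092546e-05, 1.397038655e-05, 1.558618788e-05, 1.736122324e-05, 1.930939592e-05, 2.144568752e-05, 2.378623053e-05, 2.634838489e-05, 2.915081876e-05, 3.221359349e-05, 3.555825312e-05, 3.92079184e-05, 4.318738559e-05, 4.752323011e-05, 5.224391527e-05, 5.737990611e-05, 6.296378861e-05, 6.903039426e-05, 7.561693032e-05, 8.276311563e-05, 9.051132235e-05, 9.890672353e-05, 0.0001079974468, 0.000117834734, 0.0001284731072, 0.000139970541, 0.0001523886406, 0.0001657928273, 0.0001802525293, 0.0001958413795, 0.0002126374198, 0.0002307233113, 0.0002501865515, 0.0002711196971, 0.0002936205941, 0.0003177926124, 0.0003437448884, 0.000371592572, 0.00040145708, 0.0004334663548, 0.0004677551288, 0.0005044651937, 0.0005437456743, 0.0005857533074, 0.0006306527251, 0.0006786167408, 0.0007298266402, 0.0007844724748, 0.0008427533574, 0.000904877761, 0.0009710638188, 0.001041539625, 0.001116543538, 0.001196324479, 0.001281142239, 0.001371267772, 0.001466983499, 0.001568583601, 0.001676374311, 0.001790674203, 0.001911814476, 0.002040139228, 0.002176005733, 0.002319784699, 0.002471860526, 0.002632631552, 0.00280251029, 0.00298192365, 0.003171313156, 0.003371135143, 0.003581860945, 0.003803977068, 0.00403798534, 0.004284403056, 0.004543763096, 0.004816614029, 0.00510352019, 0.005405061749, 0.005721834747, 0.006054451114, 0.006403538663, 0.00676974106, 0.007153717766, 0.007556143959, 0.007977710423, 0.008419123408, 0.008881104474, 0.009364390286, 0.009869732398, 0.010397897, 0.01094966461, 0.0115258298, 0.01212720082, 0.0127545992, 0.01340885936, 0.01409082819, 0.01480136451, 0.01554133858, 0.01631163159, 0.01711313503, 0.0179467501, 0.01881338707, 0.01971396459, 0.02064940899, 0.0216206535, 0.02262863756, 0.0236743059, 0.02475860779, 0.02588249617, 0.0270469267, 0.02825285687, 0.02950124508, 0.0307930496, 0.03212922765, 0.03351073428, 0.03493852141, 0.03641353673, 0.03793672259, 0.03950901493, 0.04113134214, 0.04280462395, 0.04452977023, 0.04630767988, 0.04813923963, 0.05002532287, 0.05196678849, 0.05396447962, 0.05601922255, 0.05813182542, 0.06030307713, 0.0625337461, 0.06482457911, 0.06717630013, 0.06958960915, 0.07206518105, 0.07460366445, 0.07720568061, 0.07987182234, 0.08260265287, 0.08539870487, 0.08826047937, 0.09118844479, 0.09418303593, 0.09724465307, 0.100373661, 0.1035703883, 0.1068351262, 0.1101681281, 0.1135696087, 0.1170397431, 0.1205786665, 0.124186473, 0.1278632157, 0.1316089057, 0.1354235116, 0.1393069593, 0.1432591315, 0.1472798672, 0.1513689617, 0.1555261661, 0.1597511873, 0.1640436876, 0.1684032852, 0.1728295533, 0.177322021, 0.1818801728, 0.186503449, 0.191191246, 0.195942916, 0.2007577681, 0.2056350679, 0.2105740387, 0.2155738611, 0.2206336741, 0.2257525756, 0.2309296228, 0.236163833, 0.2414541845, 0.2467996169, 0.2521990323, 0.2576512961, 0.2631552378, 0.268709652, 0.2743132991, 0.279964907, 0.2856631713, 0.2914067572, 0.2971942999, 0.3030244063, 0.308895656, 0.3148066024, 0.3207557741, 0.3267416761, 0.332762791, 0.3388175806, 0.3449044868, 0.3510219334, 0.3571683271, 0.3633420591, 0.3695415062, 0.3757650327, 0.3820109911, 0.3882777242, 0.3945635658, 0.400866843, 0.4071858765, 0.413518983, 0.419864476, 0.4262206673, 0.4325858686, 0.4389583925, 0.4453365541, 0.4517186723, 0.4581030711, 0.4644880808, 0.4708720396, 0.4772532944, 0.4836302025, 0.4900011323, 0.4963644652, 0.5027185959, 0.5090619345, 0.5153929066, 0.5217099552, 0.5280115414, 0.5342961453, 0.5405622673, 0.5468084288, 0.5530331732, 0.5592350669, 0.5654126998, 0.5715646866, 0.5776896671, 0.5837863074, 0.5898533001, 0.5958893654, 0.6018932515, 0.6078637352, 0.6137996226, 0.6196997494, 0.6255629815, 0.6313882154, 0.6371743788, 0.6429204305, 0.6486253612, 0.6542881935, 0.6599079823, 0.6654838149, 0.6710148114, 0.6765001245, 0.6819389399, 0.6873304763, 0.6926739854, 0.6979687519, 0.7032140935, 0.708409361, 0.7135539378, 0.7186472405, 0.7236887178, 0.7286778513, 0.7336141546, 0.7384971733, 0.7433264851, 0.7481016988, 0.7528224546, 0.7574884235, 0.7620993073, 0.7666548376, 0.771154776, 0.7755989135, 0.7799870699, 0.7843190936, 0.7885948611, 0.7928142765, 0.7969772709, 0.801083802, 0.8051338536, 0.8091274352, 0.8130645812, 0.8169453503, 0.8207698254, 0.8245381126, 0.8282503408, 0.8319066611, 0.8355072462, 0.8390522898, 0.8425420062, 0.8459766293, 0.8493564123, 0.8526816272, 0.8559525637, 0.8591695292, 0.8623328478, 0.8654428598, 0.8684999213, 0.8715044031, 0.8744566907, 0.8773571833, 0.8802062934, 0.8830044459, 0.8857520782, 0.8884496389, 0.8910975876, 0.8936963943, 0.8962465386, 0.8987485097, 0.9012028053, 0.9036099313, 0.9059704013, 0.908284736, 0.9105534627, 0.9127771149, 0.9149562318, 0.9170913575, 0.919183041, 0.9212318355, 0.9232382979, 0.9252029885, 0.9271264703, 0.9290093091, 0.9308520725, 0.9326553298, 0.9344196517, 0.9361456097, 0.9378337757, 0.939484722, 0.9410990205, 0.9426772428, 0.9442199596, 0.9457277401, 0.9472011526, 0.9486407633, 0.9500471363, 0.9514208337, 0.9527624146, 0.9540724357, 0.9553514504, 0.9566000088, 0.9578186575, 0.9590079394, 0.9601683934, 0.9613005545, 0.962404953, 0.9634821151, 0.964532562, 0.9655568103, 0.9665553717, 0.9675287527, 0.9684774546, 0.9694019733, 0.9703027994, 0.9711804177, 0.9720353076, 0.9728679426, 0.9736787904, 0.9744683128, 0.9752369657, 0.9759851986, 0.9767134555, 0.9774221738, 0.9781117848, 0.9787827137, 0.9794353793, 0.9800701944, 0.980687565, 0.9812878914, 0.981871567, 0.9824389794, 0.9829905093, 0.9835265317, 0.9840474148, 0.9845535208, 0.9850452054, 0.9855228182, 0.9859867025, 0.9864371955, 0.986874628, 0.9872993249, 0.9877116049, 0.9881117807, 0.9885001588, 0.98887704, 0.9892427191, 0.9895974849, 0.9899416204, 0.9902754032, 0.9905991047, 0.9909129911, 0.9912173226, 0.9915123543, 0.9917983356, 0.9920755106, 0.9923441181, 0.9926043916, 0.9928565594, 0.9931008449, 0.9933374662, 0.9935666365, 0.9937885642, 0.9940034529, 0.9942115013, 0.9944129036, 0.9946078492, 0.9947965233, 0.9949791062, 0.9951557743, 0.9953266993, 0.9954920489, 0.9956519867, 0.995806672, 0.9959562602, 0.996100903, 0.9962407478, 0.9963759385, 0.9965066154, 0.9966329148, 0.9967549698, 0.9968729097, 0.9969868607, 0.9970969454, 0.9972032831, 0.9973059901, 0.9974051794, 0.9975009609, 0.9975934415, 0.9976827254, 0.9977689134, 0.997852104, 0.9979323927, 0.9980098723, 0.9980846331, 0.9981567627, 0.9982263461, 0.9982934662, 0.9983582032, 0.9984206351, 0.9984808375, 0.998538884, 0.9985948458, 0.9986487921, 0.99870079, 0.9987509047, 0.9987991993, 0.9988457351, 0.9988905714, 0.9989337658, 0.9989753741, 0.9990154505, 0.9990540474, 0.9990912156, 0.9991270042, 0.9991614611, 0.9991946322, 0.9992265625, 0.9992572951, 0.999286872, 0.9993153339, 0.9993427198, 0.999369068, 0.9993944152, 0.9994187969, 0.9994422476, 0.9994648006, 0.9994864881, 0.9995073412, 0.9995273902, 0.999546664, 0.9995651909, 0.999582998, 0.9996001116, 0.9996165571, 0.9996323591, 0.9996475412, 0.9996621264, 0.9996761368, 0.9996895937, 0.9997025177, 0.9997149288, 0.9997268462, 0.9997382883, 0.9997492732, 0.999759818, 0.9997699395, 0.9997796537, 0.9997889761, 0.9997979217, 0.9998065049, 0.9998147396, 0.9998226391, 0.9998302166, 0.9998374843, 0.9998444543, 0.9998511382, 0.9998575471, 0.9998636918, 0.9998695825, 0.9998752294, 0.9998806419, 0.9998858294, 0.9998908007, 0.9998955644, 0.9999001287, 0.9999045017, 0.9999086909, 0.9999127036, 0.9999165471, 0.999920228, 0.999923753, 0.9999271283, 0.9999303601, 0.999933454, 0.9999364158, 0.9999392509, 0.9999419644, 0.9999445612, 0.9999470463, 0.9999494241, 0.9999516992, 0.9999538757, 0.9999559577, 0.9999579493, 0.9999598541, 0.9999616757, 0.9999634177, 0.9999650833, 0.9999666759, 0.9999681984, 0.9999696538, 0.9999710449, 0.9999723745, 0.9999736452, 0.9999748595, 0.9999760197, 0.9999771283, 0.9999781874, 0.9999791991, 0.9999801654, 0.9999810884, 0.9999819699, 0.9999828117, 0.9999836155, 0.9999843829, 0.9999851156, 0.999985815, 0.9999864826, 0.9999871199, 0.999987728, 0.9999883084, 0.9999888622, 0.9999893906, 0.9999898947, 0.9999903756, 0.9999908344, 0.999991272, 0.9999916893, 0.9999920873, 0.9999924668, 0.9999928287, 0.9999931737, 0.9999935027, 0.9999938162, 0.9999941151, 0.9999944, 0.9999946715, 0.9999949302, 0.9999951767, 0.9999954116, 0.9999956354, 0.9999958486, 0.9999960517, 0.9999962451, 0.9999964294, 0.9999966048, 0.9999967719, 0.999996931, 0.9999970825, 0.9999972267, 0.9999973639, 0.9999974946, 0.999997619, 0.9999977374, 0.99999785, 0.9999979572, 0.9999980592)
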