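# Reference values computed with an independent Python implementation
# (scipy.stats / pingouin) on the literal data vectors below; frozen so
# the statistics layer is checked against a second code base.

frozenShapiro <- list(
  list(x = c(-1.8423, 2.3954, 1.4985, 0.1831, -0.0056, 1.2968, -2.1197,
             -2.2867, -1.5849, -0.3524, 0.4789, -0.4252, 0.7674, 0.8358,
             0.1398, 0.6330, 0.2372, -0.6986),
       W = 0.9623530537, p = 0.6476270353),
  list(x = c(2.5459, 3.1220, 6.0090, 3.4754, 4.9900, 3.7028, 6.0443,
             6.0487, 5.6118, 6.1042, 7.6459, 6.0482, 5.2050, 7.5779,
             4.3530, 7.8350, 5.0415, 7.3128, 2.8544, 5.4705, 4.7335,
             4.4501, 6.9293, -0.0962),
       W = 0.9466663761, p = 0.2291789498),
  list(x = c(1.0777, 1.1818, 0.7031, 1.6099, 0.7783, 0.9471, 1.6615,
             1.2338, 0.6345, 1.0531, 1.2172, 0.9961),
       W = 0.9437786961, p = 0.5485153088))

frozenWelchT <- list(
  list(a = c(-0.3071, 0.2841, -1.1697, -0.5649, 0.1415, -0.5756, -0.0809,
             1.8459, -0.1306, -0.2432, 0.7033, -1.2827),
       b = c(0.0860, 1.8522, 1.5841, -0.5640, 2.8571, 0.7043, 2.7004,
             2.1705, 1.1640, 0.3739, 4.1738, -1.2175, -1.3600, 3.5929,
             3.3737, 0.8291, 1.0149),
       t = -3.1945505263, df = 25.0007980710, p = 0.0037658191),
  list(a = c(-1.4292, 0.3041, 0.0775, -0.3589, 0.5375, -0.3122, 0.8948,
             0.9258, -0.5697),
       b = c(-0.6153, 2.8634, -0.7741, -0.9004, 3.6775, 1.9203, 4.0891,
             -2.0351, 1.2035),
       t = -1.3261993078, df = 9.8471702616, p = 0.2147104147),
  list(a = c(-0.5134, -1.6296, -0.8191, -0.9275, -0.0386, -0.9556, 0.8758,
             0.1798, 0.5331, -0.1505, -0.6100, 0.0959, -0.5483, 0.9559,
             -3.6047, -1.4153, 1.3335, 2.0039, -0.0622, 1.0897),
       b = c(2.6206, 4.9465, 3.2303, 1.6413, 0.1808, -4.2253, 1.2657,
             1.3970),
       t = -1.6080610986, df = 8.2172532662, p = 0.1454902230))

frozenWelchAnova <- list(
  list(groups = list(
         g0 = c(-0.2883, 0.3515, -1.1151, 0.2059, 0.6984, -1.1189, 0.8327,
                -0.9431),
         g1 = c(-1.4099, 1.4277, 1.1010, 1.5946, -0.8502, -0.0332, 2.8140,
                2.0017, -2.3397, 1.9055, 1.5172, -1.6899),
         g2 = c(1.7520, 1.1341, 0.5754, 0.5611, 0.5296, 0.5931, 1.7201,
                1.5834, 0.7385, 1.1041, -3.4712, 2.8966, 1.4777, 0.0765,
                2.1346),
         g3 = c(-4.7746, -1.7918, -0.5907, 1.2800, 2.6743, 1.3624, -2.8148,
                -2.6008, -0.5589, 2.2444, 4.5593, -6.0838, -0.8081, -1.4612,
                -0.8014, -1.2672, -7.8209, 6.0105, 5.3814, -3.8115)),
       F = 2.0894808579, df2 = 27.1796505538, p = 0.1249194593),
  list(groups = list(
         g0 = c(-0.2936, -0.8256, 0.1912, -0.2297, -0.6998, -1.1680,
                -0.4939, 1.1163, 0.8930, 0.1696),
         g1 = c(-1.2219, -0.2057, 0.5275, 0.2802, 0.3562, 0.3735, -2.4542,
                2.4139, -0.7402, 0.9130, 0.7155, 0.7206, -0.8057, -0.0296),
         g2 = c(-0.6268, 4.4091, -2.2942, 2.9080, 7.3761, 0.9224, 0.8070,
                0.0153, 6.6806)),
       F = 2.1396187762, df2 = 16.0109961563, p = 0.1501360034))

frozenGamesHowell <- list(
  groups = list(
    a = c(-1.0286, 0.1397, -0.4856, -0.8367, 0.0177, -0.3977, -0.8194,
          1.2275, 0.0656),
    b = c(-0.4950, -2.3035, 3.9753, 0.5017, 1.4038, 1.7468, 3.5868,
          3.3356, 0.8272, 2.5019, 2.1364, 1.4636, -0.1764),
    c = c(-1.0687, 0.1083, -0.8368, 0.4487, -1.0364, 2.0037, -1.2328,
          2.6159, 1.2718, 1.3378, -0.1005, -0.2422, 0.0992, 0.7137,
          -0.3686, 0.6694, 0.1795, -0.1800)),
  pairs = data.frame(
    a = c("a", "a", "b"), b = c("b", "c", "c"),
    diff = c(-1.6586777777777777, -0.47872222222222227, 1.1799555555555556),
    df = c(16.653439679358296, 22.87960985035108, 18.099939299051478),
    p = c(0.019363640823762296, 0.3544879760925217, 0.11075302105243956)))
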