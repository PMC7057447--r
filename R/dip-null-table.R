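## Null quantiles of the dip statistic under uniform samples.
## Generated by tools/make-dip-table.R (999 replicates per n, seed
## 20200305); do not edit by hand.

DIP_NULL_PROBS <- c(0.500, 0.700, 0.800, 0.900, 0.950, 0.975, 0.990, 0.995)
DIP_NULL_N <- c(10L, 20L, 30L, 50L, 100L, 200L, 500L, 1000L, 2000)

DIP_NULL_QUANTILES <- matrix(c(
  0.098150, 0.110050, 0.119457, 0.131422, 0.139349, 0.147447, 0.159880, 0.167472,
  0.073821, 0.082631, 0.088068, 0.098052, 0.103682, 0.110895, 0.118682, 0.123139,
  0.062070, 0.069948, 0.074534, 0.081051, 0.088370, 0.093401, 0.100749, 0.103896,
  0.049133, 0.055003, 0.058438, 0.065413, 0.070779, 0.075276, 0.079360, 0.081814,
  0.035494, 0.040286, 0.043268, 0.047771, 0.051320, 0.054589, 0.057817, 0.061090,
  0.025904, 0.028929, 0.031019, 0.033606, 0.036451, 0.039552, 0.041898, 0.042836,
  0.016436, 0.018471, 0.019840, 0.021502, 0.023758, 0.025195, 0.026791, 0.028465,
  0.011615, 0.013066, 0.013905, 0.015257, 0.016570, 0.017876, 0.019530, 0.020347,
  0.008310, 0.009312, 0.010022, 0.011086, 0.012116, 0.012923, 0.014014, 0.014789
), nrow = 9L, byrow = TRUE,
  dimnames = list(as.character(DIP_NULL_N), format(DIP_NULL_PROBS)))
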