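#!/usr/bin/env Rscript
# Ligand-binding analyses: (1) one-site saturation binding at the
# cell-surface parameters (Kd 26 ug/ml, Bmax 67 ng/mg), noiseless and with
# 5% noise; (2) single-cycle SPR 1:1 kinetics at the ALK1- and
# LDLR-ectodomain injection schedules (apparent Kd 200 nM and 7 nM);
# (3) competition analysis on an independent-two-site surface;
# (4) stability-reference-point quantitation.

library(ldlscreen)
seed <- 5L

## saturation binding
sat <- gen_binding("saturation",
                   params = list(Kd = 26, Bmax = 67,
                                 conc = c(2, 5, 10, 25, 50, 100)),
                   seed = seed)
fit <- fit_saturation(sat$data$conc, sat$data$bound)
cat(sprintf("saturation (noiseless): Kd = %.2f ug/ml, Bmax = %.2f ng/mg\n",
            fit$Kd, fit$Bmax))
noisy <- gen_binding("saturation",
                     params = list(Kd = 26, Bmax = 67,
                                   conc = c(2, 5, 10, 25, 50, 100)),
                     noise = 0.05, seed = seed)
fitn <- fit_saturation(noisy$data$conc, noisy$data$bound)
cat(sprintf("saturation (5%% noise):  Kd = %.2f +- %.2f, Bmax = %.2f +- %.2f\n",
            fitn$Kd, fitn$se["Kd"], fitn$Bmax, fitn$se["Bmax"]))

## single-cycle kinetics at the two published schedules
mk_sched <- function(conc) data.frame(conc = conc, start = seq(0, 800, 200),
                                      stop = seq(0, 800, 200) + 120)
alk1 <- fit_1to1_kinetics(simulate_sensorgram(
  0.01 / 200, 0.01, 100, mk_sched(c(0.19, 0.57, 1.7, 5.1, 15.3) * 1000)))
ldlr <- fit_1to1_kinetics(simulate_sensorgram(
  0.01 / 7, 0.01, 100, mk_sched(c(5, 14, 43, 129, 388))))
cat(sprintf("SPR 1:1 fits: ALK1-ecto Kd = %.1f nM | LDLR-ecto Kd = %.2f nM\n",
            alk1$Kd, ldlr$Kd))

## competition on an independent-two-site surface: pre-saturating the other
## site leaves this analyte's kinetics untouched
sched <- mk_sched(c(0.19, 0.57, 1.7, 5.1, 15.3) * 1000)
naive <- fit_1to1_kinetics(simulate_sensorgram(0.01 / 200, 0.01, 100, sched))
pre <- gen_binding("two_site",
                   params = list(ka1 = 0.01 / 200, kd1 = 0.01, Rmax1 = 100,
                                 ka2 = 1, kd2 = 1e-4, Rmax2 = 50,
                                 schedule = sched),
                   site2_occupied = 0, seed = seed)
comp <- competition_analysis(naive, fit_1to1_kinetics(pre$data))
cat(sprintf("competition (independent sites): Kd ratio %.3f, amplitude ratio %.3f -> %s\n",
            comp$kd_ratio, comp$amplitude_ratio, comp$verdict))
shared <- fit_1to1_kinetics(simulate_sensorgram(0.01 / 200, 0.01, 4, sched))
comp2 <- competition_analysis(naive, shared)
cat(sprintf("competition (shared site):       amplitude ratio %.3f -> %s\n",
            comp2$amplitude_ratio, comp2$verdict))

## stability-reference-point quantitation
one <- data.frame(conc = 2000, start = 0, stop = 300)
ref <- simulate_sensorgram(0.01 / 200, 0.005, 100, one, time = seq(0, 420, 1))
complex_trace <- simulate_sensorgram(0.01 / 200, 0.005, 100, one,
                                     time = seq(0, 420, 1))
amp <- stability_point_quantitation(list(ref, complex_trace), ref)
cat(sprintf("stability-point amplitudes (vs ALK1-ecto alone): %.3f, %.3f\n",
            amp[1], amp[2]))
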