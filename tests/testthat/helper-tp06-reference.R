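# Independent pure-R transcription of the ten Tusscher-Panfilov 2006
# epicardial cell equations, written separately from the compiled engine and
# used as the right-hand-side oracle. Returns the 19 time-derivatives in the
# package's canonical state order.
tp06_reference_rhs <- function(y, p, i_stim = 0) {
  V <- y[["V"]]; Nai <- y[["Na_i"]]; Ki <- y[["K_i"]]
  Cai <- y[["Ca_i"]]; CaSR <- y[["Ca_SR"]]; Cass <- y[["Ca_ss"]]
  rt_f <- p$R * p$T / p$F

  E_Na <- rt_f * log(p$Na_o / Nai)
  E_K <- rt_f * log(p$K_o / Ki)
  E_Ks <- rt_f * log((p$K_o + p$p_KNa * p$Na_o) / (Ki + p$p_KNa * Nai))
  E_Ca <- rt_f / 2 * log(p$Ca_o / Cai)

  i_Na <- p$g_Na * y[["m"]]^3 * y[["h"]] * y[["j"]] * (V - E_Na)

  expz <- exp(2 * (V - 15) / rt_f)
  i_CaL <- p$g_CaL * y[["d"]] * y[["f"]] * y[["f2"]] * y[["fCass"]] * 4 *
    (V - 15) * p$F / rt_f * (0.25 * Cass * expz - p$Ca_o) / (expz - 1)

  i_to <- p$g_to * y[["r"]] * y[["s"]] * (V - E_K)
  i_Kr <- p$g_Kr * sqrt(p$K_o / 5.4) * y[["Xr1"]] * y[["Xr2"]] * (V - E_K)
  i_Ks <- p$g_Ks * y[["Xs"]]^2 * (V - E_Ks)

  a_K1 <- 0.1 / (1 + exp(0.06 * (V - E_K - 200)))
  b_K1 <- (3 * exp(2e-4 * (V - E_K + 100)) + exp(0.1 * (V - E_K - 10))) /
    (1 + exp(-0.5 * (V - E_K)))
  i_K1 <- p$g_K1 * sqrt(p$K_o / 5.4) * a_K1 / (a_K1 + b_K1) * (V - E_K)

  i_NaCa <- p$k_NaCa *
    (exp(p$gamma_ncx * V / rt_f) * Nai^3 * p$Ca_o -
       exp((p$gamma_ncx - 1) * V / rt_f) * p$Na_o^3 * Cai * p$alpha_ncx) /
    ((p$K_mNai^3 + p$Na_o^3) * (p$K_mCa + p$Ca_o) *
       (1 + p$k_sat * exp((p$gamma_ncx - 1) * V / rt_f)))

  i_NaK <- p$P_NaK * p$K_o * Nai /
    ((p$K_o + p$K_mK) * (Nai + p$K_mNa) *
       (1 + 0.1245 * exp(-0.1 * V / rt_f) + 0.0353 * exp(-V / rt_f)))

  i_pCa <- p$g_pCa * Cai / (Cai + p$K_pCa)
  i_pK <- p$g_pK * (V - E_K) / (1 + exp((25 - V) / 5.98))
  i_bNa <- p$g_bNa * (V - E_Na)
  i_bCa <- p$g_bCa * (V - E_Ca)

  dV <- -(i_K1 + i_to + i_Kr + i_Ks + i_CaL + i_NaK + i_Na + i_bNa +
            i_NaCa + i_bCa + i_pK + i_pCa + i_stim)

  kcasr <- p$max_sr - (p$max_sr - p$min_sr) / (1 + (p$EC / CaSR)^2)
  k1 <- p$k1_prime / kcasr
  k2 <- p$k2_prime * kcasr
  O <- k1 * Cass^2 * y[["Rq"]] / (p$k3 + k1 * Cass^2)
  dRq <- -k2 * Cass * y[["Rq"]] + p$k4 * (1 - y[["Rq"]])
  i_rel <- p$V_rel * O * (CaSR - Cass)
  i_leak <- p$V_leak * (CaSR - Cai)
  i_up <- p$V_maxup / (1 + p$K_up^2 / Cai^2)
  i_xfer <- p$V_xfer * (Cass - Cai)

  buf <- function(ca, b, k) 1 / (1 + b * k / (ca + k)^2)
  dCai <- buf(Cai, p$Buf_c, p$K_bufc) *
    ((i_leak - i_up) * p$V_sr / p$V_c + i_xfer -
       (i_bCa + i_pCa - 2 * i_NaCa) * p$Cm / (2 * p$V_c * p$F))
  dCaSR <- buf(CaSR, p$Buf_sr, p$K_bufsr) * (i_up - i_rel - i_leak)
  dCass <- buf(Cass, p$Buf_ss, p$K_bufss) *
    (-i_CaL * p$Cm / (2 * p$V_ss * p$F) + i_rel * p$V_sr / p$V_ss -
       i_xfer * p$V_c / p$V_ss)
  dNai <- -(i_Na + i_bNa + 3 * i_NaK + 3 * i_NaCa) * p$Cm / (p$V_c * p$F)
  dKi <- -(i_K1 + i_to + i_Kr + i_Ks + i_pK + i_stim - 2 * i_NaK) *
    p$Cm / (p$V_c * p$F)

  gate <- function(val, inf, tau) (inf - val) / tau

  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- 1 / (1 + exp((-60 - V) / 5)) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V < -40) {
    a_h <- 0.057 * exp(-(V + 80) / 6.8)
    b_h <- 2.7 * exp(0.079 * V) + 310000 * exp(0.3485 * V)
    a_j <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    b_j <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    a_h <- 0
    b_h <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    a_j <- 0
    b_j <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  tau_h <- 1 / (a_h + b_h)
  tau_j <- 1 / (a_j + b_j)
  d_inf <- 1 / (1 + exp((-8 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    1.4 / (1 + exp((V + 5) / 5)) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2_inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tau_f2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fcass_inf <- 0.6 / (1 + (Cass / 0.05)^2) + 0.4
  tau_fcass <- 80 / (1 + (Cass / 0.05)^2) + 2
  s_inf <- 1 / (1 + exp((V + 20) / 5))
  tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8

  c(V = dV,
    Xr1 = gate(y[["Xr1"]], xr1_inf, tau_xr1),
    Xr2 = gate(y[["Xr2"]], xr2_inf, tau_xr2),
    Xs = gate(y[["Xs"]], xs_inf, tau_xs),
    m = gate(y[["m"]], m_inf, tau_m),
    h = gate(y[["h"]], h_inf, tau_h),
    j = gate(y[["j"]], h_inf, tau_j),
    d = gate(y[["d"]], d_inf, tau_d),
    f = gate(y[["f"]], f_inf, tau_f),
    f2 = gate(y[["f2"]], f2_inf, tau_f2),
    fCass = gate(y[["fCass"]], fcass_inf, tau_fcass),
    s = gate(y[["s"]], s_inf, tau_s),
    r = gate(y[["r"]], r_inf, tau_r),
    Ca_i = dCai, Ca_SR = dCaSR, Ca_ss = dCass, Rq = dRq,
    Na_i = dNai, K_i = dKi)
}
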