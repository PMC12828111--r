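# Built-in truth scenarios: per dose (rows d1-d3), schedule (column blocks
# s1-s3) and subgroup, the quadruple (mu_z, p_tox, pi, u_true) where
# pi = Pr(Y > 0) and u_true is the published utility under weights
# w1 = 0.5, w2 = 0.3, w3 = 1.2 (fixed over-threshold penalty, phi_T = 0.3).
# Utilities are printed to at most two decimals; q2 is reconstructed from
# them at load time (see derive_q2_from_utility).

.scn <- function(m0, m1) {
  dimnames(m0) <- dimnames(m1) <- NULL
  list(m0 = matrix(m0, nrow = 3, byrow = TRUE),
       m1 = matrix(m1, nrow = 3, byrow = TRUE))
}

.builtin_scenarios <- list(
  .scn(
    c(3.6, 0.10, 0.45, 0.25,   7.2, 0.16, 0.45, 0.23,   8.0, 0.43, 0.45, -1.05,
      8.9, 0.14, 0.58, 0.33,  17.9, 0.18, 0.70, 0.42,  19.7, 0.55, 0.73, -0.87,
      9.8, 0.48, 0.60, -0.96, 19.7, 0.55, 0.74, -0.86, 21.6, 0.65, 0.76, -0.86),
    c(4.4, 0.10, 0.52, 0.30,   8.9, 0.16, 0.52, 0.28,   9.7, 0.43, 0.52, -1.0,
     10.9, 0.14, 0.65, 0.39,  21.9, 0.18, 0.76, 0.48,  24.0, 0.55, 0.78, -0.82,
     12.0, 0.48, 0.67, -0.9,  24.0, 0.55, 0.79, -0.8,  26.4, 0.65, 0.81, -0.8)),
  .scn(
    c(1.5, 0.05, 0.33, 0.20,   2.2, 0.08, 0.33, 0.19,   4.0, 0.10, 0.33, 0.19,
      5.1, 0.12, 0.42, 0.24,   7.6, 0.15, 0.46, 0.27,  13.9, 0.17, 0.57, 0.35,
      6.7, 0.40, 0.46, -1.0,  10.0, 0.47, 0.52, -1.0,  18.4, 0.52, 0.68, -0.86),
    c(2.2, 0.05, 0.38, 0.23,   3.2, 0.08, 0.38, 0.22,   5.9, 0.10, 0.38, 0.22,
      7.5, 0.12, 0.47, 0.28,  11.3, 0.15, 0.52, 0.30,  20.7, 0.17, 0.68, 0.39,
     10.0, 0.40, 0.51, -0.97, 14.9, 0.47, 0.57, -0.94, 27.4, 0.52, 0.72, -0.82)),
  .scn(
    c(0.9, 0.05, 0.07, 0.03,   1.3, 0.10, 0.11, 0.04,   2.6, 0.42, 0.11, -1.3,
      3.6, 0.12, 0.15, 0.06,   5.4, 0.16, 0.30, 0.14,  10.9, 0.55, 0.60, -0.94,
      5.6, 0.16, 0.23, 0.10,   8.3, 0.18, 0.50, 0.30,  16.7, 0.56, 0.89, -0.60),
    c(1.3, 0.05, 0.08, 0.04,   1.9, 0.10, 0.13, 0.05,   3.9, 0.42, 0.13, -1.2,
      5.4, 0.12, 0.17, 0.07,   8.1, 0.16, 0.34, 0.20,  16.2, 0.55, 0.62, -0.90,
      8.3, 0.16, 0.27, 0.13,  12.4, 0.18, 0.55, 0.34,  24.8, 0.56, 0.91, -0.55)),
  .scn(
    c(7.9, 0.08, 0.35, 0.24,   7.9, 0.10, 0.52, 0.39,   8.0, 0.38, 0.35, -1.05,
     10.0, 0.25, 0.40, 0.23,  10.0, 0.46, 0.57, -0.87,  10.0, 0.55, 0.40, -1.06,
     10.0, 0.56, 0.40, -1.1,  10.0, 0.58, 0.57, -0.9,   10.0, 0.65, 0.40, -1.1),
    c(13.2, 0.08, 0.40, 0.28, 13.2, 0.10, 0.57, 0.43,  13.2, 0.38, 0.40, -1.0,
     16.5, 0.25, 0.45, 0.28,  16.5, 0.46, 0.62, -0.83,  16.5, 0.55, 0.45, -1.01,
     16.5, 0.56, 0.45, -1.0,  16.5, 0.58, 0.62, -0.9,   16.5, 0.65, 0.45, -1.0)),
  .scn(
    c(8.3, 0.10, 0.29, 0.19,   8.3, 0.14, 0.40, 0.27,   8.3, 0.38, 0.31, -1.1,
     14.6, 0.15, 0.43, 0.30,  14.7, 0.16, 0.56, 0.40,  14.7, 0.45, 0.46, -0.97,
     15.0, 0.46, 0.44, -0.99, 15.0, 0.52, 0.57, -0.9,  15.0, 0.64, 0.47, -1.03),
    c(10.1, 0.10, 0.33, 0.22, 10.1, 0.14, 0.45, 0.31,  10.1, 0.38, 0.35, -1.05,
     18.0, 0.15, 0.72, 0.57,  18.0, 0.16, 0.61, 0.45,  18.0, 0.45, 0.51, -0.93,
     18.3, 0.46, 0.49, -0.95, 18.3, 0.52, 0.62, -0.85, 18.3, 0.64, 0.52, -0.98)),
  .scn(
    c(3.5, 0.05, 0.19, 0.13,   3.5, 0.08, 0.12, 0.06,   3.5, 0.10, 0.13, 0.06,
     13.2, 0.08, 0.39, 0.28,  13.2, 0.10, 0.26, 0.17,  13.2, 0.13, 0.28, 0.17,
     18.5, 0.10, 0.53, 0.39,  18.5, 0.12, 0.38, 0.25,  18.5, 0.14, 0.40, 0.27),
    c(4.3, 0.05, 0.23, 0.16,   4.3, 0.08, 0.14, 0.08,   4.3, 0.10, 0.15, 0.08,
     16.1, 0.08, 0.44, 0.32,  16.1, 0.10, 0.30, 0.20,  16.1, 0.13, 0.33, 0.21,
     22.6, 0.10, 0.54, 0.40,  22.6, 0.12, 0.43, 0.29,  22.6, 0.14, 0.72, 0.56)),
  .scn(
    c(4.3, 0.10, 0.18, 0.12,   4.3, 0.12, 0.27, 0.19,   5.2, 0.35, 0.20, -1.14,
     12.3, 0.13, 0.25, 0.17,  12.3, 0.15, 0.35, 0.26,  14.7, 0.45, 0.28, -1.1,
     14.3, 0.35, 0.27, -1.1,  14.3, 0.40, 0.38, -1.0,  17.2, 0.64, 0.31, -1.1),
    c(5.0, 0.10, 0.21, 0.15,   5.0, 0.12, 0.55, 0.45,   6.0, 0.35, 0.23, -1.11,
     14.2, 0.13, 0.29, 0.20,  14.2, 0.15, 0.40, 0.30,  17.1, 0.45, 0.33, -1.1,
     16.6, 0.35, 0.31, -1.0,  16.6, 0.40, 0.37, -1.0,  19.9, 0.64, 0.35, -1.1)),
  .scn(
    c(5.9, 0.08, 0.33, 0.26,   5.9, 0.28, 0.31, 0.18,   5.9, 0.45, 0.29, -1.1,
     13.8, 0.10, 0.42, 0.34,  13.8, 0.35, 0.40, -0.96,  13.8, 0.53, 0.38, -1.04,
     14.8, 0.12, 0.44, 0.34,  14.8, 0.42, 0.41, -0.97,  14.8, 0.64, 0.39, -1.1),
    c(6.9, 0.08, 0.38, 0.30,   6.9, 0.28, 0.35, 0.22,   6.9, 0.45, 0.33, -1.0,
     16.0, 0.10, 0.47, 0.38,  16.0, 0.35, 0.45, -0.92,  16.0, 0.53, 0.42, -0.99,
     17.2, 0.12, 0.49, 0.39,  17.2, 0.42, 0.46, -0.92,  17.2, 0.64, 0.44, -1.0)))
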