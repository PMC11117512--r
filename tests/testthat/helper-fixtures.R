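# Deterministic multi-tone test signal used to freeze wavelet oracle values.
tone_mix_237 <- function() {
  i <- 0:236
  sin(2 * pi * 7 * i / 200) + 0.5 * sin(2 * pi * 0.3 * i / 200) + 0.1 * cos(i)
}

as_ecg <- function(values, fs = 200) sampled_signal(values, fs, "ECG", "RIGHT")
as_ppg <- function(values, fs = 200) sampled_signal(values, fs, "PPG_HAND", "RIGHT")

# Evaluate the published quadratic length equations by direct arithmetic,
# independently of the length_model machinery.
hand_lengths <- function(H) {
  list(RA = -0.5263 * H^2 + 2.201 * H - 1.311,
       LA = -0.5018 * H^2 + 2.083 * H - 1.245,
       AR = -0.3993 * H^2 + 1.967 * H - 0.8949,
       AL = -0.5543 * H^2 + 2.488 * H - 1.336,
       PA = -0.2921 * H^2 + 1.055 * H - 0.736)
}

# Closed-form right-side ABI from hand arithmetic.
hand_abi_right <- function(H, ptt_hand, ptt_foot) {
  L <- hand_lengths(H)
  ((L$AR + L$PA) / ptt_foot) / (L$RA / ptt_hand)
}
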