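options(atroposcan.quiet = TRUE)

# printed slow-exchange shifts and experimental temperatures of the two tool
# compounds (VT unit set in Celsius, hence the +0.15 K offsets)
PAPER_FREQ_MHZ <- 400.13
PAPER_BARRIERS <- data.frame(
  pair = c("bi201335_pair1", "bi201335_pair2", "bi201335_pair2",
           "acbi1_pair1", "acbi1_pair1", "acbi1_pair1"),
  shift_a = c(4.46, 4.62, 4.62, 4.53, 4.53, 4.53),
  shift_b = c(4.76, 4.95, 4.95, 4.69, 4.69, 4.69),
  T_K = c(393.15, 393.15, 403.15, 393.15, 423.15, 453.15),
  dG_printed = c(18.9, 18.8, 19.3, 19.4, 20.9, 22.4)
)
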