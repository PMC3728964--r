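{
  "comment": "Reference parameter-interval box of this package (its own choice, not taken from any published table): ample enough that every vital rate can increase, decrease or stay flat with size and with time on a log-size mesh of [0, 10] over a 100-year horizon, while drawn species remain demographically viable.",
  "term":  ["s_int", "s_size", "s_time", "s_sizetime",
            "g_int", "g_size", "g_time", "g_sizetime", "g_sd",
            "f_int", "f_size", "f_time", "f_sizetime",
            "o_int", "o_time", "o_sd",
            "smax_b1", "smax_b2"],
  "lower": [-2.0, 0.05, -0.02, -0.004,
             0.3, 0.80, -0.01, -0.001, 0.25,
            -4.0, 0.10, -0.02, -0.002,
             0.3, -0.005, 0.25,
            -3.0, -0.03],
  "upper": [ 0.5, 0.50,  0.02,  0.004,
             1.0, 0.97,  0.01,  0.001, 0.70,
            -0.5, 0.60,  0.02,  0.002,
             1.5,  0.005, 0.60,
             3.0,  0.03]
}
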