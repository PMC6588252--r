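# Native-routine wrapper for the C++ greedy forward-selection engine.
forward_select_smo <- function(X, y01, fold, n_features, cost) {
  .Call(`_octexture_forward_select_smo`, X, as.integer(y01), as.integer(fold),
        as.integer(n_features), as.numeric(cost))
}
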