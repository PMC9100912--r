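.onLoad <- function(libname, pkgname) {
  # default shadow-index definition; users may register alternatives
  ndcsi_formula("rededge_amplitude", .rededge_amplitude)
}
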