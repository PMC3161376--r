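.onLoad <- function(libname, pkgname) {
  register_outcome_fn("antid", antid_outcome_fn)
}
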