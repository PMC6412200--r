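# package-level cache for the compiled manifests
.imuhar_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  # the manifest lengths are part of the package contract
  stopifnot(nrow(axis_manifest()) == 254L, nrow(rotinv_manifest()) == 90L)
  invisible()
}
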