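.onLoad <- function(libname, pkgname) {
  register_segmenter("reference_unet",
                     function(...) reference_unet(...))
}
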