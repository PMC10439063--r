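#' Re-exported generics
#'
#' \code{ranef} is re-exported from \pkg{lme4} so conditional modes can be
#' extracted from CLMM fits with the generic the field expects.
#'
#' @name reexports
#' @importFrom lme4 ranef
#' @export ranef
NULL
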