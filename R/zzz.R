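#' @importFrom EBImage imageData otsu
#' @importFrom stats median mad approx approxfun
#' @importFrom utils head tail
NULL

#' @export
EBImage::imageData
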