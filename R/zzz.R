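#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom rtracklayer export.gff3
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table download.file
NULL
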