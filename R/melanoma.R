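#' The 10-gene metastatic melanoma regulatory network
#'
#' The well-studied Boolean model of WNT5A-driven metastasis in melanoma,
#' derived from gene expression profiling studies. Genes in order from the
#' most to the least significant bit: WNT5A, PIR, S100P, RET1, MMP3, PLCG1,
#' MART1, HADHB, SNCA, STC2. Up-regulation of WNT5A is associated with
#' increased metastasis, so the undesirable states are those with `x1 = 1`
#' (see [marker_states()]). MART1 is self-regulating.
#'
#' @param p perturbation probability (default 0.01, the value used in the
#'   intervention studies of this network).
#' @return a [bnp()] with a `"genes"` attribute carrying the gene symbols.
#' @export
#' @examples
#' net <- melanoma_network()
#' pi <- steady_state(build_tpm_bnp(net))
#' undesirable_mass(pi, marker_states(10, 1, 1))  # ~0.2073
melanoma_network <- function(p = 0.01) {
  genes <- c("WNT5A", "PIR", "S100P", "RET1", "MMP3",
             "PLCG1", "MART1", "HADHB", "SNCA", "STC2")
  rules <- list(
    list(regs = c(3, 5, 6),                        # WNT5A
         f = function(x) (x[1] & x[2] & !x[3]) | (!x[2] & x[3])),
    list(regs = c(1, 3, 5),                        # PIR
         f = function(x) (!x[1] & !x[2] & x[3]) | (x[1] & !x[2] & !x[3])),
    list(regs = 7,                                 # S100P = MART1
         f = function(x) x[1]),
    list(regs = c(1, 2, 4),                        # RET1
         f = function(x) (!x[1] & x[2] & x[3]) | (!x[2] & x[3])),
    list(regs = c(4, 9),                           # MMP3
         f = function(x) (x[1] & x[2]) | (!x[2])),
    list(regs = c(4, 7, 10),                       # PLCG1
         f = function(x) (!x[1] & !x[2]) | (x[1] & x[2] & x[3])),
    list(regs = 7,                                 # MART1 (self)
         f = function(x) x[1]),
    list(regs = c(1, 5, 9),                        # HADHB
         f = function(x) (x[1] & x[2]) | (!x[2] & !x[3]) | (x[1] & !x[2] & x[3])),
    list(regs = c(1, 4, 7, 10),                    # SNCA
         f = function(x) (!x[1] & !x[3] & !x[4]) | (x[2] & !x[3] & x[4]) | x[3]),
    list(regs = 3,                                 # STC2
         f = function(x) !x[1])
  )
  tables <- vector("list", 10)
  for (i in 1:10) {
    regs <- rules[[i]]$regs
    k <- length(regs)
    inputs <- all_states(k)
    out <- apply(inputs, 1, function(row) as.integer(rules[[i]]$f(row == 1L)))
    tables[[i]] <- truth_table(i, regs, out)
  }
  net <- bnp(tables, p)
  attr(net, "genes") <- genes
  net
}
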