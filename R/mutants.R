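#' Apply an in-silico mutant transformation to a network
#'
#' Produces a modified copy of the network implementing one of the mutant
#' conditions studied in the model:
#'
#' * `"wild_type"`: unchanged copy.
#' * `"dicer_null"`: loss of microRNA biogenesis, modelled by setting the
#'   basal production offset of `mir_x` to -100, so its sigmoidal production
#'   term is effectively zero and mir-x decays to (numerically) zero.
#' * `"mirx_fast"`: accelerated mir-x turnover; the relaxation rate of
#'   `mir_x` is multiplied by 10, removing the slow-response noise filter.
#' * `"mirx_null"`: structural absence of mir-x; every interaction into and
#'   out of `mir_x` is removed and the species is clamped at zero. Distinct
#'   from `dicer_null`, which reaches zero dynamically through the -100
#'   basal offset.
#'
#' @param spec A [network_spec()] containing a `mir_x` species (not needed
#'   for `"wild_type"`).
#' @param kind One of `"wild_type"`, `"dicer_null"`, `"mirx_fast"`,
#'   `"mirx_null"`.
#' @return A new [network_spec()]; the input is never modified.
#' @export
#' @examples
#' wt <- hox_consensus_network()
#' dicer <- apply_mutant(wt, "dicer_null")
#' dicer$basal[["mir_x"]]
apply_mutant <- function(spec,
                         kind = c(
                           "wild_type", "dicer_null",
                           "mirx_fast", "mirx_null"
                         )) {
  stopifnot(inherits(spec, "network_spec"))
  kind <- match.arg(kind)
  if (kind == "wild_type") {
    return(spec)
  }
  if (!"mir_x" %in% spec$species) {
    stop("network has no `mir_x` species; cannot apply mutant `", kind, "`",
      call. = FALSE
    )
  }
  out <- spec
  switch(kind,
    dicer_null = {
      out$basal[["mir_x"]] <- -100
    },
    mirx_fast = {
      out$gamma[["mir_x"]] <- 10 * out$gamma[["mir_x"]]
    },
    mirx_null = {
      out$omega["mir_x", ] <- 0
      out$omega[, "mir_x"] <- 0
      out$clamp_zero <- union(out$clamp_zero, "mir_x")
    }
  )
  out
}
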