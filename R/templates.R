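# Bundled synthetic expression-scaffold stand-ins. The real scaffolds
# (the ScFc tag and the PGT121 acceptor Fab) are proprietary/supplementary
# sequences; these stubs reproduce only the features the design code
# depends on and are clearly labelled synthetic.

#' Bundled synthetic scaffold stand-ins
#'
#' `defaultScFcTemplate()` returns a short synthetic stand-in for a
#' TEV-cleavable, poly-His-tagged single-chain Fc tag: a linker, the
#' `ENLYFQG` TEV site, a CH2/CH3-like stub and a 10x His tract.
#' `defaultFabAcceptor()` returns a synthetic stand-in for an acceptor Fab
#' heavy chain with an extended CDRH3 stalk, plus the 0-based insertion
#' point inside that CDRH3 where a knob graft belongs.
#'
#' These are not the real expression scaffolds; substitute genuine
#' sequences for actual construct design.
#'
#' @return `defaultScFcTemplate()`: a character scalar.
#'   `defaultFabAcceptor()`: `list(heavy =, insertion_point =)`.
#' @examples
#' nchar(defaultScFcTemplate())
#' defaultFabAcceptor()$insertion_point
#' @export
defaultScFcTemplate <- function() {
  paste0("SGGGGS", "ENLYFQG", "SGAPELLGGPSVFLFPPKPKDTLMISRTPEVT",
         "GGGGSGGGGS", "APELLGGPSVFLFPPKPKDTLMISRTPEVT", "HHHHHHHHHH")
}

#' @rdname defaultScFcTemplate
#' @export
defaultFabAcceptor <- function() {
  heavy <- paste0("QVQLQESGPGLVKPSETLSLTCTVS",       # FR1-like stub
                  "GGSISS", "WGWIRQPPGKGLEWIG",      # CDR1/FR2-like stub
                  "SIYGSG", "RVTISVDTSKNQFSLKLSSVTAADTAVYYCAR",
                  "TTVHQETKKYQS",                    # extended CDRH3 stalk
                  "WGQGTLVTVSS")
  # graft point: middle of the CDRH3 stalk
  list(heavy = heavy,
       insertion_point = regexpr("TTVHQETKKYQS", heavy, fixed = TRUE)[1L]
         - 1L + 6L)
}
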