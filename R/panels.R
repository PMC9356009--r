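#' Stimulus and cytokine panels
#'
#' A stimulus panel is a data.frame with columns \code{stimulus} (unique short
#' label), \code{group} (one of \code{viral}, \code{bacterial}, \code{tcell},
#' \code{media}), \code{rank} (culture order: when too few cells were
#' recovered for the full panel, stimuli were used in rank order, so
#' missingness is monotone in rank) and \code{target_missing_rate}.
#'
#' The default panel lists the 16 culture conditions of the study design
#' (media + 15 stimuli) in culture-rank order with their per-stimulus missing
#' rates. Two adjustments keep the rates compatible with the count-based
#' (monotone-in-rank) missingness mechanism: the adjacent CpG-A/PAM rates are
#' pooled to their mean (isotonic fit), and polyIC -- whose observed rate is
#' not reported -- is interpolated from its rank neighbours.
#'
#' @return a data.frame as described.
#' @examples
#' sp <- defaultStimulusPanel()
#' subset(sp, group == "viral")$stimulus
#' @export
defaultStimulusPanel <- function() {
  sp <- data.frame(
    stimulus = c("Media", "RV16", "RSV", "Hin", "Strpn", "PHA", "RV1B",
                 "polyIC", "LPS", "R848", "CpGA", "PAM", "PGN", "FSL",
                 "Fla", "LTA"),
    group = c("media", "viral", "viral", "bacterial", "bacterial", "tcell",
              "viral", "viral", "bacterial", "viral", "viral", "bacterial",
              "bacterial", "bacterial", "bacterial", "bacterial"),
    rank = 1:16,
    target_missing_rate = c(0.007, 0.008, 0.013, 0.022, 0.029, 0.051, 0.058,
                            0.096, 0.134, 0.178, 0.3025, 0.3025, 0.331,
                            0.373, 0.445, 0.488),
    stringsAsFactors = FALSE)
  validateStimulusPanel(sp)
  sp
}

#' @rdname defaultStimulusPanel
#' @details A cytokine panel is a data.frame with columns \code{cytokine},
#'   \code{functional_group} (one of \code{anti_viral},
#'   \code{pro_inflammatory}, \code{t_cell}, \code{weak}) and per-batch lower
#'   detection limits \code{lod_batch1}, \code{lod_batch2} (pg/mL). The
#'   default 28-plex panel covers type I/II/III interferons, IFN-induced
#'   chemokines, pro-inflammatory cytokines and T-cell derived cytokines.
#' @export
defaultCytokinePanel <- function() {
  grp <- c(
    IFNa2 = "anti_viral", IP10 = "anti_viral", MCP1 = "anti_viral",
    eotaxin1 = "anti_viral", MCP4 = "anti_viral",
    IL1b = "pro_inflammatory", IL6 = "pro_inflammatory",
    IL8 = "pro_inflammatory", MIP1b = "pro_inflammatory",
    TNF = "pro_inflammatory", IL10 = "pro_inflammatory",
    MDC = "pro_inflammatory", IL17 = "pro_inflammatory",
    IFNg = "t_cell", IL2 = "t_cell", IL4 = "t_cell", IL5 = "t_cell",
    IL13 = "t_cell", IL12p70 = "t_cell",
    IFNb = "weak", IL29 = "weak", IL15 = "weak", IL16 = "weak",
    eotaxin3 = "weak", IL18 = "weak", TARC = "weak", IL7 = "weak",
    IL33 = "weak")
  cp <- data.frame(cytokine = names(grp), functional_group = unname(grp),
                   lod_batch1 = 0.8, lod_batch2 = 0.5,
                   stringsAsFactors = FALSE)
  validateCytokinePanel(cp)
  cp
}

#' Validate a stimulus panel
#'
#' Checks uniqueness of names, presence of exactly one media entry, that
#' ranks are a permutation of 1..n, and that target missing rates are
#' non-decreasing in rank among non-media stimuli (a requirement of the
#' count-based monotone missingness mechanism).
#'
#' @param sp stimulus panel data.frame.
#' @return \code{sp}, invisibly; errors if invalid.
#' @export
validateStimulusPanel <- function(sp) {
  stopifnot(is.data.frame(sp),
            all(c("stimulus", "group", "rank", "target_missing_rate") %in%
                  names(sp)))
  if (anyDuplicated(sp$stimulus)) stop("stimulus names must be unique")
  if (sum(sp$group == "media") != 1L)
    stop("exactly one media entry required")
  if (!setequal(sp$rank, seq_len(nrow(sp))))
    stop("ranks must be a permutation of 1..n")
  if (!all(sp$group %in% c("viral", "bacterial", "tcell", "media")))
    stop("unknown stimulus group")
  if (any(sp$target_missing_rate < 0 | sp$target_missing_rate > 1))
    stop("target_missing_rate must lie in [0, 1]")
  ns <- sp[sp$group != "media", ]
  ns <- ns[order(ns$rank), ]
  if (any(diff(ns$target_missing_rate) < 0))
    stop("target missing rates must be non-decreasing in rank")
  invisible(sp)
}

#' @rdname validateStimulusPanel
#' @param cp cytokine panel data.frame.
#' @export
validateCytokinePanel <- function(cp) {
  stopifnot(is.data.frame(cp),
            all(c("cytokine", "functional_group", "lod_batch1",
                  "lod_batch2") %in% names(cp)))
  if (anyDuplicated(cp$cytokine)) stop("cytokine names must be unique")
  if (any(cp$lod_batch1 <= 0) || any(cp$lod_batch2 <= 0))
    stop("every LOD must be > 0")
  if (!all(cp$functional_group %in%
             c("anti_viral", "pro_inflammatory", "t_cell", "weak")))
    stop("unknown functional group")
  invisible(cp)
}

#' Name of the media control in a stimulus panel
#' @param sp stimulus panel.
#' @return character scalar.
#' @export
mediaName <- function(sp) sp$stimulus[sp$group == "media"]

#' Default cytokine-stimulus specificity groups
#'
#' The six predefined pair groups used to profile how specific a cQTL is to
#' IL-6/bacterial responses: IL-6 x other bacterial stimuli (n = 7), IL-6 x
#' viral stimuli (n = 4), other pro-inflammatory cytokines x bacterial
#' stimuli (n = 56), virus-induced cytokines x viral stimuli (n = 16), other
#' pro-inflammatory cytokines x PHA (n = 7) and virus-induced cytokines x
#' PHA (n = 4). Membership is configuration, not hard-coded biology.
#'
#' @param indexStimulus the bacterial stimulus of the index association,
#'   excluded from group 1.
#' @return named list of data.frames with columns cytokine, stimulus.
#' @export
defaultSpecificityGroups <- function(indexStimulus = "Fla") {
  bacterial <- c("Hin", "Strpn", "LPS", "PAM", "PGN", "FSL", "Fla", "LTA")
  viral4 <- c("RSV", "RV16", "R848", "CpGA")
  proinf_other <- c("IL1b", "IL8", "MIP1b", "TNF", "IL17", "MCP1", "MCP4")
  virus_induced <- c("IFNa2", "IP10", "eotaxin1", "MCP4")
  pairs <- function(ck, st) expand.grid(cytokine = ck, stimulus = st,
                                        stringsAsFactors = FALSE)
  list(
    il6_bacterial   = pairs("IL6", setdiff(bacterial, indexStimulus)),
    il6_viral       = pairs("IL6", viral4),
    proinf_bacterial = pairs(proinf_other, bacterial),
    virus_viral     = pairs(virus_induced, viral4),
    proinf_pha      = pairs(proinf_other, "PHA"),
    virus_pha       = pairs(virus_induced, "PHA"))
}
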