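#' Construct a CytokineExperiment
#'
#' @param concentrations named list of cytokine x child matrices (one per
#'   stimulus, pg/mL, \code{NA} = missing) or a 3-D array
#'   cytokine x child x stimulus.
#' @param batch per-child batch label ("1"/"2").
#' @param viability per-child viability percentage.
#' @param stimulusPanel,cytokinePanel panel data.frames (defaults:
#'   \code{\link{defaultStimulusPanel}}, \code{\link{defaultCytokinePanel}}).
#' @return a \linkS4class{CytokineExperiment}.
#' @export
CytokineExperiment <- function(concentrations, batch, viability,
                               stimulusPanel = defaultStimulusPanel(),
                               cytokinePanel = defaultCytokinePanel()) {
  if (is.array(concentrations) && length(dim(concentrations)) == 3L) {
    concentrations <- lapply(seq_len(dim(concentrations)[3]), function(i)
      concentrations[, , i])
    names(concentrations) <- dimnames(concentrations[[1]])$stimulus
  }
  validateStimulusPanel(stimulusPanel)
  validateCytokinePanel(cytokinePanel)
  concentrations <- concentrations[stimulusPanel$stimulus]
  rd <- DataFrame(cytokine = cytokinePanel$cytokine,
                  functional_group = cytokinePanel$functional_group,
                  lod_batch1 = cytokinePanel$lod_batch1,
                  lod_batch2 = cytokinePanel$lod_batch2,
                  row.names = cytokinePanel$cytokine)
  cd <- DataFrame(batch = as.character(batch), viability = viability,
                  row.names = colnames(concentrations[[1]]))
  se <- SummarizedExperiment(assays = concentrations, rowData = rd,
                             colData = cd)
  metadata(se)$stimulusPanel <- stimulusPanel
  metadata(se)$cytokinePanel <- cytokinePanel
  new("CytokineExperiment", se)
}

#' Panel, child and batch accessors
#'
#' @param x a CytokineExperiment or FoldMatrix.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
stimulusPanel <- function(x) metadata(x)$stimulusPanel

#' @rdname accessors
#' @export
cytokinePanel <- function(x) metadata(x)$cytokinePanel

#' @rdname accessors
#' @export
stimuli <- function(x) {
  if (is(x, "CytokineExperiment")) assayNames(x) else
    unique(rowData(x)$stimulus)
}

#' @rdname accessors
#' @export
cytokines <- function(x) {
  if (is(x, "CytokineExperiment")) rownames(x) else
    unique(rowData(x)$cytokine)
}

#' @rdname accessors
#' @export
children <- function(x) colnames(x)

#' @rdname accessors
#' @export
childBatch <- function(x) {
  b <- colData(x)$batch
  names(b) <- colnames(x)
  b
}

#' @rdname accessors
#' @export
childViability <- function(x) {
  v <- colData(x)$viability
  names(v) <- colnames(x)
  v
}

#' Per-batch lower detection limits
#' @param x a CytokineExperiment.
#' @param batch batch label ("1" or "2").
#' @return named numeric vector, one LOD per cytokine (pg/mL).
#' @export
lodOf <- function(x, batch) {
  stopifnot(batch %in% c("1", "2"))
  col <- paste0("lod_batch", batch)
  v <- rowData(x)[[col]]
  names(v) <- rownames(x)
  v
}

#' Extract one (cytokine, stimulus) response vector across children
#' @param x a CytokineExperiment.
#' @param cytokine,stimulus names resolvable against the panels.
#' @return named numeric vector (pg/mL).
#' @export
responseOf <- function(x, cytokine, stimulus) {
  if (!stimulus %in% assayNames(x)) stop("unknown stimulus: ", stimulus)
  if (!cytokine %in% rownames(x)) stop("unknown cytokine: ", cytokine)
  assay(x, stimulus)[cytokine, ]
}

#' Construct a FoldMatrix from a pair x child log2 fold matrix
#'
#' @param log2fold matrix, rows named "cytokine.stimulus".
#' @param pairInfo data.frame with columns cytokine, stimulus (row order
#'   matching \code{log2fold}).
#' @param stimulusPanel,cytokinePanel panels.
#' @param imputed optional logical matrix of the same shape.
#' @return a \linkS4class{FoldMatrix}.
#' @export
FoldMatrix <- function(log2fold, pairInfo, stimulusPanel, cytokinePanel,
                       imputed = NULL) {
  rd <- DataFrame(
    cytokine = pairInfo$cytokine, stimulus = pairInfo$stimulus,
    cytokine_group = cytokinePanel$functional_group[
      match(pairInfo$cytokine, cytokinePanel$cytokine)],
    stimulus_group = stimulusPanel$group[
      match(pairInfo$stimulus, stimulusPanel$stimulus)],
    row.names = rownames(log2fold))
  al <- list(log2fold = log2fold)
  if (!is.null(imputed)) al$imputed <- imputed
  se <- SummarizedExperiment(assays = al, rowData = rd)
  metadata(se)$stimulusPanel <- stimulusPanel
  metadata(se)$cytokinePanel <- cytokinePanel
  new("FoldMatrix", se)
}

#' Construct a GenotypeSet
#'
#' @param dosage SNP x child matrix of minor-allele dosages in [0, 2].
#' @param snpInfo data.frame with columns chrom, pos, ref, alt, typed,
#'   call_rate, info, maf, hwe_p (row order matching \code{dosage}).
#' @return a \linkS4class{GenotypeSet}.
#' @export
GenotypeSet <- function(dosage, snpInfo) {
  rd <- DataFrame(snpInfo, row.names = rownames(dosage))
  new("GenotypeSet",
      SummarizedExperiment(assays = list(dosage = dosage), rowData = rd))
}

#' @rdname accessors
#' @export
dosages <- function(x) assay(x, "dosage")

#' Matrix of log2 fold inductions (children as rows)
#' @param x a FoldMatrix.
#' @return child x pair numeric matrix.
#' @export
foldValues <- function(x) t(assay(x, "log2fold"))
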