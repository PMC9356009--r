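#' Write a CytokineExperiment as a long-format TSV
#'
#' Canonical tidy layout with header child_id, batch, viability_pct,
#' stimulus, cytokine, concentration_pg_ml, lod_pg_ml; missing
#' concentrations are encoded as empty fields. One row per
#' (child, stimulus, cytokine).
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @param path output file.
#' @export
writeCytokineTable <- function(x, path) {
  b <- childBatch(x); v <- childViability(x)
  rows <- list()
  for (s in assayNames(x)) {
    a <- assay(x, s)
    rows[[s]] <- data.frame(
      child_id = rep(colnames(a), each = nrow(a)),
      batch = rep(b, each = nrow(a)),
      viability_pct = rep(v, each = nrow(a)),
      stimulus = s,
      cytokine = rep(rownames(a), ncol(a)),
      concentration_pg_ml = as.vector(a),
      lod_pg_ml = as.vector(ifelse(rep(b, each = nrow(a)) == "1",
                                   rowData(x)$lod_batch1, rowData(x)$lod_batch2)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$child_id, out$stimulus, out$cytokine), ]
  conc <- ifelse(is.na(out$concentration_pg_ml), "",
                 format(out$concentration_pg_ml, digits = 17, trim = TRUE,
                        scientific = FALSE))
  out$concentration_pg_ml <- conc
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format cytokine TSV into a CytokineExperiment
#'
#' Rejects malformed headers, duplicate (child, stimulus, cytokine) rows,
#' negative concentrations, and stimulus/cytokine names absent from the
#' panels. Per-batch LODs are taken from the file and must be consistent
#' within (cytokine, batch).
#'
#' @param path input TSV.
#' @param stimulusPanel,cytokinePanel panels used to validate names and
#'   supply group metadata.
#' @return a \linkS4class{CytokineExperiment}.
#' @export
readCytokineTable <- function(path, stimulusPanel = defaultStimulusPanel(),
                              cytokinePanel = defaultCytokinePanel()) {
  need <- c("child_id", "batch", "viability_pct", "stimulus", "cytokine",
            "concentration_pg_ml", "lod_pg_ml")
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, need))
    stop("malformed header: expected ", paste(need, collapse = ", "))
  tb <- utils::read.delim(path, colClasses = c(
    child_id = "character", batch = "character", viability_pct = "numeric",
    stimulus = "character", cytokine = "character",
    concentration_pg_ml = "character", lod_pg_ml = "numeric"))
  dup <- duplicated(tb[c("child_id", "stimulus", "cytokine")])
  if (any(dup)) {
    d <- tb[which(dup)[1], ]
    stop("duplicate row for (", d$child_id, ", ", d$stimulus, ", ",
         d$cytokine, ")")
  }
  if (!all(tb$stimulus %in% stimulusPanel$stimulus))
    stop("unknown stimulus in table")
  if (!all(tb$cytokine %in% cytokinePanel$cytokine))
    stop("unknown cytokine in table")
  conc <- suppressWarnings(as.numeric(tb$concentration_pg_ml))
  conc[tb$concentration_pg_ml == ""] <- NA
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentrations")
  kids <- unique(tb$child_id)
  cyt <- cytokinePanel$cytokine
  used <- unique(tb$stimulus)
  sp <- stimulusPanel[stimulusPanel$stimulus %in% used, ]
  sp$rank <- rank(sp$rank)  # re-rank when the file covers a panel subset
  assaysL <- lapply(stats::setNames(sp$stimulus, sp$stimulus), function(s)
    matrix(NA_real_, length(cyt), length(kids),
           dimnames = list(cyt, kids)))
  for (s in sp$stimulus) {
    sub <- tb[tb$stimulus == s, ]
    idx <- cbind(match(sub$cytokine, cyt), match(sub$child_id, kids))
    assaysL[[s]][idx] <- conc[tb$stimulus == s]
  }
  first <- tb[!duplicated(tb$child_id), ]
  cp <- cytokinePanel
  for (bt in c("1", "2")) {
    sub <- tb[tb$batch == bt, ]
    if (nrow(sub)) {
      lods <- tapply(sub$lod_pg_ml, sub$cytokine, function(z) {
        u <- unique(z)
        if (length(u) > 1) stop("inconsistent LOD within cytokine/batch")
        u
      })
      col <- paste0("lod_batch", bt)
      vals <- as.numeric(lods[match(cp$cytokine, names(lods))])
      vals[is.na(vals)] <- cp[[col]][is.na(vals)]  # panel default fallback
      cp[[col]] <- vals
    }
  }
  CytokineExperiment(assaysL, first$batch[match(kids, first$child_id)],
                     first$viability_pct[match(kids, first$child_id)],
                     sp, cp)
}

#' Write a GenotypeSet as VCF v4.2 with dosages
#'
#' Emits a minimal VCF with the imputation info score in the INFO column
#' (key \code{INFO}), a \code{TYPED} flag for genotyped markers, and
#' per-sample \code{GT:DS} fields; missing calls are \code{./.:.}.
#'
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param path output file.
#' @export
writeVCF <- function(genotypes, path) {
  rd <- rowData(genotypes)
  dos <- dosages(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Genotyped (not imputed)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Minor allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t")), con)
  gtOf <- function(d) {
    ifelse(is.na(d), "./.:.",
           paste0(c("0/0", "0/1", "1/1")[round(d) + 1], ":",
                  format(d, trim = TRUE)))
  }
  for (i in seq_len(nrow(dos))) {
    info <- sprintf("INFO=%g%s", rd$info[i],
                    if (rd$typed[i]) ";TYPED" else "")
    writeLines(paste(c(rd$chrom[i], rd$pos[i], rownames(dos)[i], rd$ref[i],
                       rd$alt[i], ".", "PASS", info, "GT:DS",
                       gtOf(dos[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Prefers the DS FORMAT field; falls back to GT converted to 0/1/2
#' minor-allele counts. The per-SNP info score is read from the INFO key
#' \code{INFO} (defaulting to 1 when absent), typed status from the
#' \code{TYPED} flag. Call rate, MAF and exact HWE p are recomputed from
#' the dosages.
#'
#' @param path VCF file.
#' @return a \linkS4class{GenotypeSet}.
#' @export
readGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    fmt[gt %in% c("0/0", "0|0")] <- 0
    fmt[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    fmt[gt %in% c("1/1", "1|1")] <- 2
  }
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  ids <- fix[, "ID"]
  rownames(fmt) <- ids
  infoStr <- fix[, "INFO"]
  getInfo <- function(key) {
    m <- regmatches(infoStr, regexpr(paste0(key, "=[^;]+"), infoStr))
    out <- rep(NA_real_, length(infoStr))
    hit <- grepl(paste0(key, "="), infoStr)
    out[hit] <- as.numeric(sub(paste0(key, "="), "", m))
    out
  }
  info <- getInfo("INFO")
  info[is.na(info)] <- 1
  typed <- grepl("(^|;)TYPED(;|$)", infoStr)
  call_rate <- rowMeans(!is.na(fmt))
  af <- rowMeans(fmt, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(fmt, 1, function(g) {
    g <- round(g[!is.na(g)])
    if (!length(g)) return(NA_real_)
    hweExact(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  GenotypeSet(fmt, data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], typed = typed,
    call_rate = call_rate, info = info, maf = maf, hwe_p = hwe_p,
    stringsAsFactors = FALSE))
}

#' Write a FoldMatrix as a long TSV
#'
#' Columns: child_id, cytokine, stimulus, log2_fold (empty = missing),
#' imputed (TRUE/FALSE; FALSE when no imputation has run).
#'
#' @param folds a \linkS4class{FoldMatrix}.
#' @param path output file.
#' @export
writeFoldTable <- function(folds, path) {
  m <- assay(folds, "log2fold")
  imp <- if ("imputed" %in% assayNames(folds)) assay(folds, "imputed") else
    matrix(FALSE, nrow(m), ncol(m))
  rd <- rowData(folds)
  out <- data.frame(
    child_id = rep(colnames(m), each = nrow(m)),
    cytokine = rep(rd$cytokine, ncol(m)),
    stimulus = rep(rd$stimulus, ncol(m)),
    log2_fold = ifelse(is.na(as.vector(m)), "",
                       format(as.vector(m), digits = 17, trim = TRUE)),
    imputed = as.vector(imp), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a signature model as YAML
#'
#' The generating truth of a synthetic cohort, written as a structured text
#' config so recovery tests can reload it.
#'
#' @param model a \code{"SignatureModel"}.
#' @param path YAML file.
#' @export
writeSignatureModel <- function(model, path) {
  enc <- function(m) list(rownames = rownames(m), colnames = colnames(m),
                          rows = lapply(seq_len(nrow(m)),
                                        function(i) unname(m[i, ])))
  obj <- list(
    media_baseline = as.list(model$media_baseline),
    signature = enc(model$signature),
    child_reactivity_sd = as.list(model$child_reactivity_sd),
    batch_shift = enc(model$batch_shift),
    noise_sd = model$noise_sd,
    genetic_effects = as.list(model$genetic_effects),
    phenotype_links = as.list(model$phenotype_links),
    inadequate_rate = model$inadequate_rate,
    low_viability_rate = model$low_viability_rate,
    phenotype_prevalence = model$phenotype_prevalence)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(path) {
  obj <- yaml::read_yaml(path)
  dec <- function(l) {
    m <- do.call(rbind, lapply(l$rows, unlist))
    dimnames(m) <- list(unlist(l$rownames), unlist(l$colnames))
    m
  }
  signatureModel(
    media_baseline = unlist(obj$media_baseline),
    signature = dec(obj$signature),
    child_reactivity_sd = unlist(obj$child_reactivity_sd),
    batch_shift = dec(obj$batch_shift),
    noise_sd = obj$noise_sd,
    genetic_effects = as.data.frame(obj$genetic_effects,
                                    stringsAsFactors = FALSE),
    phenotype_links = as.data.frame(obj$phenotype_links,
                                    stringsAsFactors = FALSE),
    inadequate_rate = obj$inadequate_rate,
    low_viability_rate = obj$low_viability_rate,
    phenotype_prevalence = obj$phenotype_prevalence)
}
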