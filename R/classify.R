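# feature columns interpreted as evidence for each substrate
.asp_transporter_cols <- c("gltI", "peb1A", "aapJ", "abc_pa_s",
                           "gltP", "gltT", "gltTK", "gltPh", "ybeC")
.asp_pathway_cols <- c("atcase")
.ace_pathway_cols <- c("ack_pta", "acs")

#' Estimate genome size from assembly statistics
#'
#' \deqn{Size_{est} = (Size_{obs} - Size_{obs} \cdot contamination) / completeness}
#'
#' @param size_obs observed (binned) genome size in bp.
#' @param completeness estimated completeness, fraction in (0, 1].
#' @param contamination estimated contamination, fraction in `[0, 1)`.
#' @return estimated complete genome size in bp.
#' @examples
#' estimate_genome_size(2e6, 0.95, 0.05)  # 2e6
#' @export
estimate_genome_size <- function(size_obs, completeness, contamination) {
  if (any(completeness <= 0) || any(completeness > 1))
    stop("completeness must lie in (0, 1]")
  if (any(contamination < 0) || any(contamination >= 1))
    stop("contamination must lie in [0, 1)")
  if (any(size_obs < 0)) stop("size_obs must be nonnegative")
  (size_obs - size_obs * contamination) / completeness
}

#' Select the representative genome for a taxon
#'
#' Filters candidate genomes to 16S identity strictly above `identity_min`,
#' then ranks by (i) geographic priority of the source spring
#' (Gongxiaoshe, then Jinze, then Rehai, then other), (ii) MAG quality score
#' `completeness - 5 * contamination`, (iii) 16S identity, with ties broken
#' by lexicographically smallest genome id.
#'
#' @param candidates data frame of genome features for one taxon; must carry
#'   `genome`, `source_spring`, `identity_16S`, `completeness`,
#'   `contamination`.
#' @param identity_min 16S identity threshold in percent (default 95).
#' @return the selected row of `candidates`, or `NULL` when none passes the
#'   identity filter.
#' @export
select_representative <- function(candidates, identity_min = 95) {
  need <- c("genome", "source_spring", "identity_16S", "completeness",
            "contamination")
  if (!is.data.frame(candidates) || !all(need %in% names(candidates)))
    stop("candidates must carry columns: ", paste(need, collapse = ", "))
  ok <- candidates[candidates$identity_16S > identity_min, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  priority <- match(ok$source_spring,
                    c("Gongxiaoshe", "Jinze", "Rehai"), nomatch = 4L)
  quality <- ok$completeness - 5 * ok$contamination
  ord <- order(priority, -quality, -ok$identity_16S, ok$genome)
  ok[ord[1], , drop = FALSE]
}

#' Keep the highest AFE per genome
#'
#' When several taxa map to the same representative genome, only the call
#' with the maximal median AFE is retained for that genome (first record on
#' exact ties).
#'
#' @param calls data frame with at least `genome` and `afe_median`.
#' @return the deduplicated data frame, one row per genome.
#' @export
resolve_duplicate_afe <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("genome", "afe_median") %in% names(calls)))
  if (nrow(calls) == 0) return(calls)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), calls$genome), function(i) {
    v <- calls$afe_median[i]
    if (all(is.na(v))) i[1] else i[which.max(v)]
  }), use.names = FALSE)
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# evidence booleans for one feature row
.feature_evidence <- function(feats, substrate) {
  present <- function(cols) {
    cols <- intersect(cols, names(feats))
    length(cols) > 0 && any(unlist(feats[cols]) > 0)
  }
  if (substrate == "aspartate") {
    list(transporter = present(.asp_transporter_cols),
         pathway = present(.asp_pathway_cols))
  } else {
    list(transporter = present("actP"),
         pathway = present(.ace_pathway_cols))
  }
}

#' Classify one taxon as primary utilizer or cross-feeder
#'
#' Combines the qSIP AFE evidence with genome features. For aspartate, a
#' primary utilizer needs a positive median AFE, at least one aspartate
#' transporter (ABC substrate-binding protein or symporter), and the
#' assimilation pathway (ATCase); for acetate the transporter requirement is
#' waived because acetic acid diffuses across membranes, so a positive AFE
#' plus ACK-PTA or ACS suffices. Taxa with positive AFE but no genomic
#' machinery are cross-feeders; nonpositive AFE means non-utilizer; emergent
#' taxa are unscored; taxa without a matched genome are `"no-genome"`.
#'
#' @param substrate `"acetate"` or `"aspartate"`.
#' @param afe_median the taxon's median AFE (may be `NA` for emergent taxa).
#' @param emergent logical: was the taxon flagged emergent?
#' @param features a one-row data frame of genome features, or `NULL` when
#'   no genome is matched.
#' @param ci_low optional lower CI bound; used instead of the median when
#'   `positive = "ci"`.
#' @param positive `"median"` (default: positive means `afe_median > 0`) or
#'   `"ci"` (the 90% CI must exclude zero from below).
#' @return list with `class` (one of `primary`, `cross-feeder`,
#'   `non-utilizer`, `emergent-unscored`, `no-genome`) and `evidence`
#'   (character summary of which criteria fired).
#' @export
classify_utilizer <- function(substrate, afe_median, emergent = FALSE,
                              features = NULL, ci_low = NA_real_,
                              positive = c("median", "ci")) {
  substrate <- match.arg(substrate, c("acetate", "aspartate"))
  positive <- match.arg(positive)
  if (isTRUE(emergent))
    return(list(class = "emergent-unscored",
                evidence = "absent before labeling; no AFE"))
  if (is.null(features) || nrow(features) == 0)
    return(list(class = "no-genome", evidence = "no matched genome"))
  is_pos <- if (positive == "median") isTRUE(afe_median > 0)
            else isTRUE(ci_low > 0)
  if (!is_pos)
    return(list(class = "non-utilizer", evidence = "nonpositive AFE"))
  ev <- .feature_evidence(features, substrate)
  genomic_ok <- if (substrate == "aspartate") ev$transporter && ev$pathway
                else ev$pathway
  summary <- sprintf("AFE>0; transporter=%s; pathway=%s",
                     ev$transporter, ev$pathway)
  if (genomic_ok) list(class = "primary", evidence = summary)
  else list(class = "cross-feeder", evidence = summary)
}

#' Classify every scored taxon of an AFE table
#'
#' Table-level driver: selects a representative genome per taxon
#' ([select_representative()]), applies [classify_utilizer()] to every
#' scored or emergent taxon, and optionally resolves duplicate AFE values per
#' genome ([resolve_duplicate_afe()]).
#'
#' @param afe data frame from [qsip_afe()].
#' @param features genome-feature table (several candidate genomes per taxon
#'   allowed).
#' @param identity_min 16S identity threshold in percent (default 95).
#' @param dedupe_genomes keep only the highest-AFE call per genome (default
#'   `FALSE`).
#' @inheritParams classify_utilizer
#' @return data frame: `taxon`, `substrate`, `class`, `afe_median`,
#'   `genome`, `evidence`.
#' @export
classify_utilizers <- function(afe, features, identity_min = 95,
                               positive = c("median", "ci"),
                               dedupe_genomes = FALSE) {
  positive <- match.arg(positive)
  stopifnot(is.data.frame(afe),
            all(c("taxon", "substrate", "afe_median", "status") %in% names(afe)))
  use <- afe[afe$status %in% c("scored", "emergent"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(use)), function(i) {
    tx <- use$taxon[i]
    cand <- features[features$taxon == tx, , drop = FALSE]
    rep_g <- if (nrow(cand) > 0) select_representative(cand, identity_min)
             else NULL
    call <- classify_utilizer(use$substrate[i], use$afe_median[i],
                              emergent = use$status[i] == "emergent",
                              features = rep_g,
                              ci_low = if ("ci_low" %in% names(use))
                                use$ci_low[i] else NA_real_,
                              positive = positive)
    data.frame(taxon = tx, substrate = use$substrate[i], class = call$class,
               afe_median = use$afe_median[i],
               genome = if (is.null(rep_g)) NA_character_ else rep_g$genome,
               evidence = call$evidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(taxon = character(), substrate = character(),
                      class = character(), afe_median = numeric(),
                      genome = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (dedupe_genomes) {
    with_g <- !is.na(out$genome)
    out <- rbind(resolve_duplicate_afe(out[with_g, , drop = FALSE]),
                 out[!with_g, , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Read a genome-feature table
#'
#' Tab-separated text with one row per candidate genome; boolean flags as
#' 0/1.
#'
#' @param path file path.
#' @return data frame with logical flag columns.
#' @export
read_genome_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  flag_cols <- intersect(c(.asp_transporter_cols, "actP",
                           .asp_pathway_cols, .ace_pathway_cols), names(df))
  for (cl in flag_cols) df[[cl]] <- as.logical(df[[cl]] > 0)
  df
}
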