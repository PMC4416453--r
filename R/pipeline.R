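# The end-to-end meta-analysis: load the lineage/disjunction table, compute
# rate tables across nested clade levels and an epsilon grid, build the
# fastest-family reference envelope, classify clades against it, compute
# clade probabilities and stem-crown gaps, and bin disjunction ages into
# geological stages.

.split_types <- c("W-E", "W-E&S", "E-S")
.levels <- c("disjunct-clade", "section", "subgenus", "genus", "tribe",
             "subfamily", "family")

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' rf_extdata()
#' rf_extdata("rf_lineages.tsv")
#' @export
rf_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "randflora")))
  path <- system.file("extdata", file, package = "randflora")
  if (!nzchar(path)) .stop_domain("no packaged file '%s'", file)
  path
}

#' Load and validate a lineage/disjunction table
#'
#' The table is tab-separated with one row per clade observation or dated
#' disjunction and columns `row_id`, `parent_id`, `kind` (`clade` |
#' `disjunction`), `lineage`, `name`, `level`, `split_type` (`W-E`, `W-E&S`,
#' `E-S`; disjunction rows only), `age_ma`, `crown_age_ma`, `stem_age_ma`,
#' `n_species`, `source_note`; missing values are `NA`. `parent_id` links
#' each row to its encompassing clade; links must be acyclic, an encompassing
#' row's richness must be at least its nested row's, and ages must weakly
#' increase with nesting.
#'
#' The packaged table (`rf_extdata("rf_lineages.tsv")`) encodes the 21 dated
#' Rand Flora disjunctions with their encompassing clades; see its
#' `source_note` column for the provenance class of each value (published
#' split ages and crown/stem pairs vs. approximate, replaceable richness).
#'
#' @param path Path to a TSV file; defaults to the packaged table.
#' @return A validated data frame of class `c("lineage_table", "data.frame")`.
#' @examples
#' tab <- load_lineage_table()
#' table(tab$kind)
#' @export
load_lineage_table <- function(path = rf_extdata("rf_lineages.tsv")) {
  if (!file.exists(path)) .stop_domain("lineage table file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA", quote = "", comment.char = "")
  required <- c("row_id", "parent_id", "kind", "lineage", "name", "level",
                "split_type", "age_ma", "crown_age_ma", "stem_age_ma",
                "n_species", "source_note")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    .stop_domain("lineage table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) .stop_domain("no records in lineage table")
  if (anyDuplicated(tab$row_id))
    .stop_domain("duplicated row_id: %s",
                 paste(unique(tab$row_id[duplicated(tab$row_id)]), collapse = ", "))
  bad <- which(!tab$kind %in% c("clade", "disjunction"))
  if (length(bad)) .stop_domain("row %s: unknown kind '%s'",
                                tab$row_id[bad[1L]], tab$kind[bad[1L]])
  bad <- which(!tab$level %in% .levels)
  if (length(bad)) .stop_domain("row %s: unknown level '%s'",
                                tab$row_id[bad[1L]], tab$level[bad[1L]])
  dj <- tab$kind == "disjunction"
  bad <- which(dj & !tab$split_type %in% .split_types)
  if (length(bad)) .stop_domain("row %s: unknown split_type '%s'",
                                tab$row_id[bad[1L]], tab$split_type[bad[1L]])
  for (col in c("age_ma", "crown_age_ma", "stem_age_ma")) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] <= 0)
    if (length(bad)) .stop_domain("row %s: %s must be a positive age",
                                  tab$row_id[bad[1L]], col)
  }
  bad <- which(dj & is.na(tab$age_ma))
  if (length(bad)) .stop_domain("row %s: disjunction rows need age_ma",
                                tab$row_id[bad[1L]])
  bad <- which(is.na(tab$crown_age_ma) & is.na(tab$stem_age_ma))
  if (length(bad)) .stop_domain("row %s: needs at least one of crown_age_ma/stem_age_ma",
                                tab$row_id[bad[1L]])
  both <- !is.na(tab$crown_age_ma) & !is.na(tab$stem_age_ma)
  bad <- which(both & tab$stem_age_ma <= tab$crown_age_ma)
  if (length(bad)) .stop_domain("row %s: stem_age_ma must exceed crown_age_ma",
                                tab$row_id[bad[1L]])
  if (anyNA(tab$n_species) || any(tab$n_species < 1))
    .stop_domain("n_species must be present and >= 1 on every row")
  bad <- which(dj & !is.na(tab$crown_age_ma) & tab$n_species < 2)
  if (length(bad)) .stop_domain("row %s: crown-dated disjunction rows need n_species >= 2",
                                tab$row_id[bad[1L]])

  # nesting links: existence, acyclicity, monotone richness and ages
  pidx <- match(tab$parent_id, tab$row_id)
  bad <- which(!is.na(tab$parent_id) & is.na(pidx))
  if (length(bad)) .stop_domain("row %s: parent_id '%s' not in table",
                                tab$row_id[bad[1L]], tab$parent_id[bad[1L]])
  for (i in seq_len(nrow(tab))) {
    seen <- i; j <- pidx[i]
    while (!is.na(j)) {
      if (j %in% seen) .stop_domain("row %s: cyclic nesting link", tab$row_id[i])
      seen <- c(seen, j); j <- pidx[j]
    }
  }
  has_parent <- which(!is.na(pidx))
  p <- pidx[has_parent]
  bad <- has_parent[tab$n_species[p] < tab$n_species[has_parent]]
  if (length(bad)) .stop_domain("row %s: richer than its encompassing row",
                                tab$row_id[bad[1L]])
  for (col in c("crown_age_ma", "stem_age_ma")) {
    ok <- !is.na(tab[[col]][has_parent]) & !is.na(tab[[col]][p])
    bad <- has_parent[ok][tab[[col]][p][ok] < tab[[col]][has_parent][ok]]
    if (length(bad)) .stop_domain("row %s: %s exceeds its encompassing row's",
                                  tab$row_id[bad[1L]], col)
  }
  structure(tab, class = c("lineage_table", "data.frame"))
}

#' @export
print.lineage_table <- function(x, ...) {
  cat(sprintf("Lineage table: %d rows (%d disjunctions, %d encompassing clades)\n",
              nrow(x), sum(x$kind == "disjunction"), sum(x$kind == "clade")))
  NextMethod()
}

# age used under each basis: explicit crown/stem age, falling back to the
# disjunction's split age as its crown age
.basis_age <- function(tab, basis) {
  if (basis == "crown") {
    t <- tab$crown_age_ma
    t[is.na(t) & tab$kind == "disjunction"] <- tab$age_ma[is.na(t) & tab$kind == "disjunction"]
  } else {
    t <- tab$stem_age_ma
  }
  t
}

#' Method-of-moments rate table across the epsilon grid
#'
#' One net diversification estimate per row, extinction fraction and basis.
#' The two-taxon adjustment is applied throughout (at every `epsilon`, since
#' two-taxon clades are reported under all extinction scenarios). Rows
#' lacking the age a basis requires get an explicit `not computable` note,
#' never a silent drop.
#'
#' @param table A [load_lineage_table()] result.
#' @param epsilons Extinction fractions; default `c(0, 0.5, 0.9)`.
#' @param basis `"crown"`, `"stem"` or `"both"`.
#' @return Data frame with columns `row_id`, `name`, `level`, `kind`,
#'   `basis`, `epsilon`, `n`, `n_adj`, `t`, `r_hat`, `note`.
#' @examples
#' rates <- compute_rate_table(load_lineage_table(), epsilons = 0)
#' head(rates)
#' @export
compute_rate_table <- function(table, epsilons = c(0, 0.5, 0.9),
                               basis = c("both", "crown", "stem")) {
  basis <- match.arg(basis)
  .check_epsilon(epsilons)
  bases <- if (basis == "both") c("crown", "stem") else basis
  out <- list()
  for (b in bases) {
    t_b <- .basis_age(table, b)
    for (eps in epsilons) {
      n_adj <- ifelse(table$n_species == 2, 2.01, table$n_species)
      r_hat <- rep(NA_real_, nrow(table))
      note <- rep("", nrow(table))
      for (i in seq_len(nrow(table))) {
        if (is.na(t_b[i])) {
          note[i] <- paste("not computable: no", b, "age")
        } else if (b == "crown" && n_adj[i] < 2) {
          note[i] <- "not computable: n < 2 on crown basis"
        } else {
          r_hat[i] <- if (b == "crown")
            crown_rate(n_adj[i], t_b[i], eps)$r_hat
          else stem_rate(table$n_species[i], t_b[i], eps)$r_hat
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        row_id = table$row_id, name = table$name, level = table$level,
        kind = table$kind, basis = b, epsilon = eps, n = table$n_species,
        n_adj = n_adj, t = t_b, r_hat = r_hat, note = note,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reference envelope from the fastest family
#'
#' Estimates crown-basis rates for every family-level row, selects the family
#' with the highest rate (per extinction fraction), and builds
#' expected-diversity confidence envelopes through time at that reference
#' rate — the background against which disjunct clades are judged
#' unexpectedly species-poor or species-rich.
#'
#' @inheritParams compute_rate_table
#' @param conf Confidence level; default 0.95.
#' @param times Time grid in Myr; default 201 points spanning the oldest age
#'   in the table (with 5\% headroom).
#' @param basis Basis for the reference rate and tail (default `"crown"`,
#'   matching the standard analysis; stem-age points are classified against
#'   this same envelope).
#' @return Class `"reference_envelope"`: list with `envelopes` (one
#'   [diversity_limits()] per epsilon, named by epsilon), `family` (selected
#'   family per epsilon), `rates` (family-by-epsilon rate table), `conf`,
#'   `basis`, `times`.
#' @examples
#' ref <- reference_envelope(load_lineage_table(), epsilons = 0)
#' ref$family
#' @export
reference_envelope <- function(table, conf = 0.95, epsilons = c(0, 0.5, 0.9),
                               times = NULL, basis = c("crown", "stem")) {
  basis <- match.arg(basis)
  fam <- table[table$level == "family", , drop = FALSE]
  if (nrow(fam) == 0L) .stop_domain("no family-level rows in table")
  if (is.null(times)) {
    tmax <- max(c(fam$crown_age_ma, table$age_ma, table$crown_age_ma,
                  table$stem_age_ma), na.rm = TRUE) * 1.05
    times <- seq(0, tmax, length.out = 201L)
  }
  rates <- compute_rate_table(fam, epsilons = epsilons, basis = basis)
  rates <- rates[!is.na(rates$r_hat), , drop = FALSE]
  if (nrow(rates) == 0L) .stop_domain("no computable family-level rates")
  envelopes <- list(); family <- character(0)
  for (eps in epsilons) {
    re <- rates[rates$epsilon == eps, , drop = FALSE]
    best <- re[which.max(re$r_hat), , drop = FALSE]
    family[as.character(eps)] <- best$name
    envelopes[[as.character(eps)]] <-
      diversity_limits(best$r_hat, eps, times, conf = conf, basis = basis)
  }
  structure(list(envelopes = envelopes, family = family, rates = rates,
                 conf = conf, basis = basis, times = times),
            class = "reference_envelope")
}

#' @export
print.reference_envelope <- function(x, ...) {
  cat(sprintf("Reference expected-diversity envelopes (%s basis, conf = %g)\n",
              x$basis, x$conf))
  for (eps in names(x$envelopes))
    cat(sprintf("  epsilon = %s: %s, r_ref = %.4f\n", eps, x$family[eps],
                attr(x$envelopes[[eps]], "r_ref")))
  invisible(x)
}

#' Classify clades against the reference envelope
#'
#' Each row is placed below, within or above the reference envelope at its
#' own age: `below` if `n < lower(t)`, `above` if `n > upper(t)`, otherwise
#' `within` — the interval is closed, so a clade sitting exactly on a bound
#' classifies as within. Bounds are evaluated exactly at the row's age (the
#' envelope parameters, not grid interpolation); ages beyond the envelope's
#' time grid are an error advising grid extension. The tail probability
#' `P(N >= n)` under the reference law at the row's age is reported
#' alongside, together with the row's stem-crown gap where defined.
#'
#' @param table A [load_lineage_table()] result.
#' @param ref A [reference_envelope()].
#' @param basis Which age to classify at: `"crown"`, `"stem"` or `"both"`
#'   (rows lacking an age on a basis are skipped for that basis).
#' @return Data frame of class `"clade_classification"`: `row_id`, `name`,
#'   `level`, `kind`, `basis`, `epsilon`, `n`, `t`, `lower`, `upper`,
#'   `position`, `tail_prob`, `stem_crown_gap`.
#' @examples
#' tab <- load_lineage_table()
#' ref <- reference_envelope(tab, epsilons = 0)
#' cls <- classify_clades(tab, ref, basis = "crown")
#' subset(cls, position == "below", c(name, n, t, lower))
#' @export
classify_clades <- function(table, ref, basis = c("both", "crown", "stem")) {
  basis <- match.arg(basis)
  stopifnot(inherits(ref, "reference_envelope"))
  bases <- if (basis == "both") c("crown", "stem") else basis
  tmax <- max(ref$times)
  gap <- ifelse(!is.na(table$crown_age_ma) & !is.na(table$stem_age_ma),
                table$stem_age_ma - table$crown_age_ma, NA_real_)
  out <- list()
  for (b in bases) {
    t_b <- .basis_age(table, b)
    keep <- which(!is.na(t_b))
    for (eps_name in names(ref$envelopes)) {
      env <- ref$envelopes[[eps_name]]
      eps <- attr(env, "epsilon"); r_ref <- attr(env, "r_ref")
      conf <- attr(env, "conf"); tail_basis <- attr(env, "basis")
      for (i in keep) {
        t <- t_b[i]
        if (t > tmax)
          .stop_domain("row %s: age %g Ma exceeds the envelope time grid (max %g); extend 'times'",
                       table$row_id[i], t, tmax)
        beta <- .beta_param(r_ref, eps, t)
        lower <- .bound_one(beta, (1 + conf) / 2, tail_basis)
        upper <- .bound_one(beta, (1 - conf) / 2, tail_basis)
        n <- table$n_species[i]
        position <- if (n < lower) "below" else if (n > upper) "above" else "within"
        tail_prob <- if (n %% 1 == 0) {
          if (tail_basis == "crown") {
            if (n >= 2) prob_geq_crown(n, r_ref, eps, t) else NA_real_
          } else prob_geq_stem(n, r_ref, eps, t)
        } else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          row_id = table$row_id[i], name = table$name[i],
          level = table$level[i], kind = table$kind[i], basis = b,
          epsilon = eps, n = n, t = t, lower = lower, upper = upper,
          position = position, tail_prob = tail_prob,
          stem_crown_gap = gap[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("clade_classification", "data.frame")
  res
}

#' Probability of each disjunct clade given its encompassing clade's rate
#'
#' For every disjunction row, the probability of obtaining a clade at least
#' as large, at the row's own age, under the background rate estimated for
#' its encompassing clade (recomputed per extinction fraction). Crown basis
#' uses the both-founders-survive tail, so two-taxon clades have probability
#' 1 by construction. Probabilities are reported raw (no multiple-testing
#' correction), mirroring how such meta-analyses present them.
#'
#' @inheritParams compute_rate_table
#' @return Data frame: `row_id`, `name`, `parent`, `basis`, `epsilon`, `n`,
#'   `t`, `r_encompassing`, `prob`, `note`.
#' @examples
#' probs <- clade_probability(load_lineage_table(), epsilons = 0)
#' head(probs[order(probs$prob), c("name", "prob")])
#' @export
clade_probability <- function(table, basis = c("crown", "stem"),
                              epsilons = c(0, 0.5, 0.9)) {
  basis <- match.arg(basis)
  .check_epsilon(epsilons)
  dj <- which(table$kind == "disjunction")
  pidx <- match(table$parent_id, table$row_id)
  bad <- dj[is.na(pidx[dj])]
  if (length(bad))
    .stop_domain("row %s: disjunction lacks an encompassing (parent) row",
                 table$row_id[bad[1L]])
  t_child <- .basis_age(table, basis)
  t_parent <- .basis_age(table, basis)
  out <- list()
  for (eps in epsilons) {
    for (i in dj) {
      p <- pidx[i]
      n_p <- ifelse(table$n_species[p] == 2, 2.01, table$n_species[p])
      note <- ""; r_p <- NA_real_; prob <- NA_real_
      if (is.na(t_parent[p]) || is.na(t_child[i])) {
        note <- paste("not computable: missing", basis, "age")
      } else {
        r_p <- if (basis == "crown") crown_rate(n_p, t_parent[p], eps)$r_hat
               else stem_rate(table$n_species[p], t_parent[p], eps)$r_hat
        n_i <- table$n_species[i]
        prob <- if (basis == "crown") prob_geq_crown(n_i, r_p, eps, t_child[i])
                else prob_geq_stem(n_i, r_p, eps, t_child[i])
      }
      out[[length(out) + 1L]] <- data.frame(
        row_id = table$row_id[i], name = table$name[i],
        parent = table$name[p], basis = basis, epsilon = eps,
        n = table$n_species[i], t = t_child[i], r_encompassing = r_p,
        prob = prob, note = note, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stem-crown gaps
#'
#' `stem_age - crown_age` per row, sorted descending; wide gaps (default
#' flag threshold 10 Myr) are the classical signature of lineages whose
#' early diversity was pruned by extinction. Rows missing either age are
#' skipped with a notice.
#'
#' @inheritParams compute_rate_table
#' @param flag_threshold Gap (Myr) above which a row is flagged.
#' @return Data frame: `row_id`, `name`, `kind`, `crown_age_ma`,
#'   `stem_age_ma`, `gap`, `flagged`, sorted by decreasing gap.
#' @examples
#' head(stem_crown_gap(load_lineage_table()))
#' @export
stem_crown_gap <- function(table, flag_threshold = 10) {
  has <- !is.na(table$crown_age_ma) & !is.na(table$stem_age_ma)
  if (any(!has))
    message(sum(!has), " row(s) without both ages skipped")
  x <- table[has, , drop = FALSE]
  gap <- x$stem_age_ma - x$crown_age_ma
  res <- data.frame(row_id = x$row_id, name = x$name, kind = x$kind,
                    crown_age_ma = x$crown_age_ma, stem_age_ma = x$stem_age_ma,
                    gap = gap, flagged = gap > flag_threshold,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$gap), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Load a geological stage table
#'
#' Stages are `(name, older bound, younger bound)` in Ma, contiguous,
#' non-overlapping and strictly decreasing. The packaged default carries the
#' International Chronostratigraphic Chart bounds for the Burdigalian through
#' the Pleistocene — the span of the Rand Flora disjunctions.
#'
#' @param path TSV with columns `stage`, `older_ma`, `younger_ma`.
#' @return Data frame of class `c("stage_table", "data.frame")`.
#' @examples
#' load_stage_table()
#' @export
load_stage_table <- function(path = rf_extdata("geological_stages.tsv")) {
  st <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("stage", "older_ma", "younger_ma") %in% names(st)))
    .stop_domain("stage table needs columns stage, older_ma, younger_ma")
  if (any(st$older_ma <= st$younger_ma))
    .stop_domain("each stage's older bound must exceed its younger bound")
  if (is.unsorted(rev(st$older_ma), strictly = TRUE))
    .stop_domain("stages must be ordered old to young with strictly decreasing bounds")
  if (nrow(st) > 1L && any(st$younger_ma[-nrow(st)] != st$older_ma[-1L]))
    .stop_domain("stages must be contiguous (each younger bound = next older bound)")
  structure(st, class = c("stage_table", "data.frame"))
}

#' Assign ages to geological stages
#'
#' Each age falls in the unique stage whose half-open interval
#' `(younger_ma, older_ma]` contains it. Ages within `snap_tol` of an
#' interior stage boundary are additionally flagged as boundary cases (the
#' assignment itself stays strict). Ages outside the table's overall span
#' are an error.
#'
#' @param age Ages in Ma before present.
#' @param stages A [load_stage_table()] result.
#' @param snap_tol Boundary flag tolerance in Myr; default 0 (no flags).
#' @return Data frame: `age_ma`, `stage`, `boundary`.
#' @examples
#' assign_stage(c(17.4, 11, 6.5, 4), load_stage_table())
#' @export
assign_stage <- function(age, stages = load_stage_table(), snap_tol = 0) {
  if (!is.numeric(age) || anyNA(age)) .stop_domain("'age' must be numeric")
  oldest <- max(stages$older_ma); youngest <- min(stages$younger_ma)
  if (any(age > oldest))
    .stop_domain("age %g Ma is older than the oldest stage bound (%g Ma)",
                 max(age), oldest)
  if (any(age <= youngest))
    .stop_domain("age %g Ma is younger than the youngest stage bound (%g Ma)",
                 min(age), youngest)
  idx <- vapply(age, function(a)
    which(a <= stages$older_ma & a > stages$younger_ma)[1L], integer(1))
  interior <- stages$older_ma[-1L]
  boundary <- vapply(age, function(a)
    any(abs(a - interior) <= snap_tol), logical(1))
  data.frame(age_ma = age, stage = stages$stage[idx], boundary = boundary,
             stringsAsFactors = FALSE)
}

#' Bin disjunction ages into geological stages
#'
#' Applies [assign_stage()] to every disjunction row of a lineage table. The
#' default boundary tolerance is 0.3 Myr: the disjunction ages are reported
#' at roughly half-Myr ("ca.") precision, so ages that close to a stage
#' boundary are surfaced as boundary cases rather than silently binned.
#'
#' @inheritParams compute_rate_table
#' @param stages A [load_stage_table()] result.
#' @param snap_tol Boundary flag tolerance in Myr.
#' @return Data frame: `row_id`, `name`, `split_type`, `age_ma`, `stage`,
#'   `boundary`, ordered old to young.
#' @examples
#' bin_disjunction_stages(load_lineage_table())
#' @export
bin_disjunction_stages <- function(table, stages = load_stage_table(),
                                   snap_tol = 0.3) {
  dj <- table[table$kind == "disjunction", , drop = FALSE]
  if (nrow(dj) == 0L) .stop_domain("no disjunction rows in table")
  s <- assign_stage(dj$age_ma, stages, snap_tol = snap_tol)
  res <- data.frame(row_id = dj$row_id, name = dj$name,
                    split_type = dj$split_type, age_ma = dj$age_ma,
                    stage = s$stage, boundary = s$boundary,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$age_ma), , drop = FALSE]
  rownames(res) <- NULL
  res
}
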