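#' Code the early-pregnancy binary trait
#'
#' A heifer that calves at less than 31 months of age is a success (1); calving
#' at 31 months or later is a failure (0). The caller is responsible for
#' restricting input to heifers exposed at around 16 months.
#'
#' @param calving_age_months numeric vector of ages at first calving (months).
#' @return integer vector of 0/1 codes.
#' @export
code_early_pregnancy <- function(calving_age_months) {
  if (any(!is.finite(calving_age_months)) || any(calving_age_months <= 0))
    stop("calving age must be positive and finite")
  as.integer(calving_age_months < 31)
}

#' Form contemporary groups from the five CG fields
#'
#' The contemporary group is the combination of year of birth, farm, and
#' management group at birth, weaning and yearling. The derived \code{cg_id}
#' is the canonical concatenation of the five fields, so records with
#' identical fields always share a group.
#'
#' Records with a missing CG field are excluded and logged rather than
#' grouped.
#'
#' @param records data.frame with columns \code{year_birth}, \code{farm},
#'   \code{mg_birth}, \code{mg_weaning}, \code{mg_yearling}.
#' @return list with \code{records} (input plus \code{cg_id}) and \code{audit}
#'   (data.frame of excluded records: record_id, rule, detail).
#' @export
form_contemporary_groups <- function(records) {
  fields <- c("year_birth", "farm", "mg_birth", "mg_weaning", "mg_yearling")
  missing_f <- setdiff(fields, names(records))
  if (length(missing_f) > 0)
    stop("missing CG field column(s): ", paste(missing_f, collapse = ", "))
  bad <- rowSums(is.na(records[fields])) > 0
  audit <- if (any(bad)) {
    data.frame(record_id = as.character(records$animal[bad]),
               rule = "missing_cg_field",
               detail = vapply(which(bad), function(i)
                 paste(fields[is.na(records[i, fields])], collapse = ","), ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = character(0), rule = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
  keep <- records[!bad, , drop = FALSE]
  keep$cg_id <- do.call(paste, c(lapply(fields, function(f) as.character(keep[[f]])),
                                 sep = "|"))
  list(records = keep, audit = audit)
}

#' Apply the contemporary-group record filters
#'
#' For the binary trait, contemporary groups without variability (all records
#' in the same response category) are removed whole. For the continuous trait,
#' records lying outside the group mean plus or minus three within-group
#' standard deviations are removed. Afterwards, for both traits, groups left
#' with fewer than four records are removed; the minimum-size rule is checked
#' once more after its own removals settle group membership (no full loop).
#'
#' The within-group standard deviation uses the sample (n-1) denominator; a
#' group of one record has undefined SD and its record is retained by the
#' outlier rule (then caught by the minimum-size rule).
#'
#' @param records data.frame with \code{animal}, \code{trait}, \code{cg_id}.
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @return list with \code{records} (filtered) and \code{audit} (data.frame
#'   record_id, rule, detail).
#' @export
filter_records <- function(records, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  empty_audit <- data.frame(record_id = character(0), rule = character(0),
                            detail = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(list(records = records, audit = empty_audit))
  if (is.null(records$cg_id)) stop("cg_id not assigned; run form_contemporary_groups first")
  audit <- empty_audit
  log_rm <- function(rows, rule, detail) {
    if (length(rows) == 0) return()
    audit <<- rbind(audit, data.frame(record_id = as.character(records$animal[rows]),
                                      rule = rule, detail = detail,
                                      stringsAsFactors = FALSE))
    keep_mask[rows] <<- FALSE
  }
  keep_mask <- rep(TRUE, nrow(records))

  if (trait_type == "binary") {
    if (!all(records$trait %in% c(0L, 1L)))
      stop("binary trait values must be 0 or 1")
    for (g in unique(records$cg_id)) {
      rows <- which(records$cg_id == g)
      if (length(unique(records$trait[rows])) == 1L)
        log_rm(rows, "no_variability", sprintf("cg=%s all=%s", g, records$trait[rows[1]]))
    }
  } else {
    for (g in unique(records$cg_id)) {
      rows <- which(records$cg_id == g)
      if (length(rows) < 2L) next              # SD undefined; size rule handles it
      mu <- mean(records$trait[rows])
      s <- stats::sd(records$trait[rows])
      if (s == 0) next
      out <- rows[abs(records$trait[rows] - mu) > 3 * s]
      log_rm(out, "outlier_3sd", sprintf("cg=%s mean=%.4g sd=%.4g", g, mu, s))
    }
  }

  # minimum-size rule, applied twice (its removals can empty no further group
  # below 4 except the ones it just touched, so two passes suffice)
  for (pass in 1:2) {
    tab <- table(records$cg_id[keep_mask])
    small <- names(tab)[tab < 4L]
    rows <- which(keep_mask & records$cg_id %in% small)
    log_rm(rows, "cg_min_size", sprintf("pass=%d", pass))
  }
  list(records = records[keep_mask, , drop = FALSE], audit = audit)
}

#' One-call phenotype preparation
#'
#' Runs \code{\link{form_contemporary_groups}} then \code{\link{filter_records}}
#' and merges the audit logs.
#'
#' @inheritParams form_contemporary_groups
#' @inheritParams filter_records
#' @return list with \code{records} and \code{audit}.
#' @export
prepare_phenotypes <- function(records, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  cg <- if (is.null(records$cg_id)) form_contemporary_groups(records)
        else list(records = records, audit = NULL)
  fl <- filter_records(cg$records, trait_type)
  audit <- rbind(cg$audit, fl$audit)
  list(records = fl$records, audit = audit)
}
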