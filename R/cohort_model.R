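# Pedigree and phenotype domain model: pedigree validation, affected-member
# selection, and the 5-level fundus grade assignment used to phenotype AMD.

#' Assign an AMD severity grade from structured eye findings
#'
#' Grades an individual on a 5-level scale from per-eye maximum drusen size and
#' presence of geographic atrophy (GA) or choroidal neovascularization (CNV).
#' Per-eye drusen severity: grade 1 for none or drusen < 63 um, grade 2 for
#' 63--124 um, grade 3 for 125 um and above (large and very large drusen share
#' one grade). GA or CNV overrides drusen: grade 4 when exactly one eye shows
#' GA or CNV, grade 5 when both do. Without GA/CNV the individual receives the
#' worse eye's drusen grade.
#'
#' @param drusen_um numeric length-2, maximum drusen diameter in micrometres
#'   per eye (order irrelevant); must be non-negative.
#' @param ga logical length-2, geographic atrophy per eye.
#' @param cnv logical length-2, choroidal neovascularization per eye.
#' @return list with `grade` (integer 1..5) and `category` (one of
#'   "None or small drusen", "Medium drusen", "Large or very large drusen",
#'   "Advanced AMD"). Grades 4 and 5 always map to "Advanced AMD".
#' @examples
#' assign_amd_grade(c(70, 70), c(FALSE, FALSE), c(FALSE, FALSE)) # grade 2
#' assign_amd_grade(c(0, 0), c(TRUE, FALSE), c(FALSE, FALSE))    # grade 4
#' @export
assign_amd_grade <- function(drusen_um, ga, cnv) {
  if (length(drusen_um) != 2L || length(ga) != 2L || length(cnv) != 2L) {
    stop("findings must describe exactly two eyes")
  }
  if (anyNA(drusen_um) || any(drusen_um < 0)) {
    stop("drusen sizes must be non-negative numbers")
  }
  ga <- as.logical(ga)
  cnv <- as.logical(cnv)
  if (anyNA(ga) || anyNA(cnv)) stop("GA/CNV flags must be TRUE or FALSE")

  advanced_eyes <- sum(ga | cnv) # an eye with both GA and CNV counts once
  drusen_grade <- ifelse(drusen_um < 63, 1L, ifelse(drusen_um <= 124, 2L, 3L))
  grade <- if (advanced_eyes == 2L) {
    5L
  } else if (advanced_eyes == 1L) {
    4L
  } else {
    max(drusen_grade)
  }
  categories <- c(
    "None or small drusen", "Medium drusen",
    "Large or very large drusen", "Advanced AMD", "Advanced AMD"
  )
  list(grade = grade, category = categories[[grade]])
}

.unknown_parent <- function(x) is.na(x) | x %in% c("0", "")

#' Validate a pedigree table
#'
#' Checks the structural invariants of a pedigree: unique individual ids within
#' each family, parents that either are both unknown (founder) or both resolve
#' to members of the same family, sex consistency of named fathers/mothers, and
#' acyclicity of the parentage graph. Violations are returned as data, not
#' raised as errors.
#'
#' @param ped data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` ("male"/"female"/"unknown"), `affection`
#'   ("affected"/"unaffected"/"unknown"). Unknown parents are `NA` or `"0"`.
#' @return data.frame with columns `family_id`, `individual_id`, `rule`,
#'   `detail`; zero rows iff the pedigree is well formed.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  req <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  missing_cols <- setdiff(req, names(ped))
  if (length(missing_cols)) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- list()
  add <- function(fam, id, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      family_id = fam, individual_id = id, rule = rule, detail = detail,
      stringsAsFactors = FALSE
    )
  }

  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, , drop = FALSE]
    dup <- unique(p$individual_id[duplicated(p$individual_id)])
    for (id in dup) add(fam, id, "duplicate_id", "individual_id not unique within family")

    ids <- p$individual_id
    for (i in seq_len(nrow(p))) {
      id <- p$individual_id[i]
      f <- p$father_id[i]
      m <- p$mother_id[i]
      f_unk <- .unknown_parent(f)
      m_unk <- .unknown_parent(m)
      if (xor(f_unk, m_unk)) {
        add(fam, id, "single_parent", "father and mother must be both unknown or both given")
      }
      if (!f_unk && !(f %in% ids)) {
        add(fam, id, "parent_unresolved", paste0("father '", f, "' is not a member of family ", fam))
      }
      if (!m_unk && !(m %in% ids)) {
        add(fam, id, "parent_unresolved", paste0("mother '", m, "' is not a member of family ", fam))
      }
    }

    fathers <- unique(p$father_id[!.unknown_parent(p$father_id)])
    for (f in intersect(fathers, ids)) {
      sx <- p$sex[match(f, ids)]
      if (!sx %in% c("male", "unknown")) {
        add(fam, f, "parent_sex", "individual named as father has sex female")
      }
    }
    mothers <- unique(p$mother_id[!.unknown_parent(p$mother_id)])
    for (m in intersect(mothers, ids)) {
      sx <- p$sex[match(m, ids)]
      if (!sx %in% c("female", "unknown")) {
        add(fam, m, "parent_sex", "individual named as mother has sex male")
      }
    }

    # cycle detection by iterative founder peeling; whoever survives sits on a
    # cycle (is its own ancestor)
    resolved <- character(0)
    remaining <- ids
    repeat {
      p_rem <- p[match(remaining, ids), , drop = FALSE]
      peel <- remaining[
        (.unknown_parent(p_rem$father_id) | p_rem$father_id %in% resolved |
          !p_rem$father_id %in% remaining) &
          (.unknown_parent(p_rem$mother_id) | p_rem$mother_id %in% resolved |
            !p_rem$mother_id %in% remaining)
      ]
      peel <- setdiff(peel, resolved)
      if (!length(peel)) break
      resolved <- c(resolved, peel)
      remaining <- setdiff(remaining, peel)
      if (!length(remaining)) break
    }
    for (id in remaining) add(fam, id, "cycle", "individual is its own ancestor")
  }

  if (!length(out)) {
    return(data.frame(
      family_id = character(0), individual_id = character(0),
      rule = character(0), detail = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Affected members of a pedigree
#'
#' Returns the ids of affected individuals, optionally restricted to those with
#' genotype data. Individuals with affection "unknown" are never counted.
#'
#' @param ped pedigree data.frame (see [validate_pedigree()]).
#' @param genotyped_only if TRUE, intersect with `sample_ids`.
#' @param sample_ids character vector of genotyped sample ids (required when
#'   `genotyped_only = TRUE`).
#' @return character vector of individual ids.
#' @export
affected_members <- function(ped, genotyped_only = FALSE, sample_ids = NULL) {
  ids <- ped$individual_id[ped$affection == "affected"]
  if (genotyped_only) {
    if (is.null(sample_ids)) stop("sample_ids required when genotyped_only = TRUE")
    ids <- intersect(ids, sample_ids)
  }
  ids
}

.topological_order <- function(ped) {
  ids <- ped$individual_id
  ordered <- character(0)
  remaining <- ids
  while (length(remaining)) {
    p_rem <- ped[match(remaining, ids), , drop = FALSE]
    ready <- remaining[
      (.unknown_parent(p_rem$father_id) | p_rem$father_id %in% ordered) &
        (.unknown_parent(p_rem$mother_id) | p_rem$mother_id %in% ordered)
    ]
    if (!length(ready)) stop("pedigree parentage graph contains a cycle")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

.is_founder <- function(ped, id) {
  i <- match(id, ped$individual_id)
  if (is.na(i)) stop("unknown individual '", id, "'")
  .unknown_parent(ped$father_id[i]) && .unknown_parent(ped$mother_id[i])
}
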