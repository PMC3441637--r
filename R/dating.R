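## Parsimony dating of loci and ORFs. The model is Dollo with a single gain
## and no losses: a character (locus or intact ORF) arises once on a branch
## and is never lost. Any presence profile that would force a loss is
## discarded as "contradictory" rather than modelled, so every dated branch
## is the branch immediately above the most recent common ancestor of the
## species carrying the character.

PRESENCE_STATES <- c("present", "absent", "ambiguous")

#' Build a presence profile
#'
#' @param states named character vector mapping species to
#'   `"present"`, `"absent"` or `"ambiguous"`.
#' @param entity `"locus"` or `"orf"` (bookkeeping only).
#' @return an object of class `presence_profile`.
#' @export
presence_profile <- function(states, entity = c("orf", "locus")) {
  entity <- match.arg(entity)
  if (is.null(names(states)) || any(names(states) == ""))
    stop("states must be a named vector (species -> state)")
  bad <- setdiff(unique(states), PRESENCE_STATES)
  if (length(bad))
    stop("invalid presence state(s): ", paste(bad, collapse = ", "))
  structure(list(entity = entity, states = states),
            class = "presence_profile")
}

#' Assign an origination branch by single-gain/zero-loss parsimony
#'
#' The dated branch is the branch immediately above the MRCA of all
#' `"present"` leaves, provided (i) every leaf inside that clade is present
#' or ambiguous and (ii) at least one out-group leaf is unambiguously
#' absent (so an older origin is excluded). A profile with an absent leaf
#' inside the clade would require a loss and is `"contradictory"`; a
#' profile whose out-groups are all ambiguous (or with no present leaf at
#' all) is `"undatable"`. When the present set spans the whole tree the
#' branch above the root is assigned with `presence_support = 0`.
#'
#' @param tree rooted `phylo` object.
#' @param profile a [presence_profile()] (or a bare named state vector).
#' @return an object of class `age_assignment`: list with `branch` (branch
#'   id or `NA`), `status` (`"dated"`, `"contradictory"` or `"undatable"`)
#'   and `presence_support` (number of unambiguously absent out-groups).
#' @export
assign_age <- function(tree, profile) {
  if (!inherits(profile, "presence_profile"))
    profile <- presence_profile(profile)
  states <- profile$states
  missing_sp <- setdiff(names(states), tree$tip.label)
  if (length(missing_sp))
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  present <- names(states)[states == "present"]
  if (length(present) == 0L)
    return(new_age_assignment(NA_character_, "undatable", 0L))
  clade <- mrca_leafset(tree, present)
  inside <- states[intersect(names(states), clade)]
  if (any(inside == "absent"))
    return(new_age_assignment(NA_character_, "contradictory", 0L))
  outgroups <- setdiff(tree$tip.label, clade)
  out_states <- states[intersect(names(states), outgroups)]
  support <- sum(out_states == "absent")
  if (length(outgroups) > 0L && support == 0L)
    return(new_age_assignment(NA_character_, "undatable", 0L))
  new_age_assignment(branch_id(clade), "dated", as.integer(support))
}

new_age_assignment <- function(branch, status, support) {
  structure(list(branch = branch, status = status,
                 presence_support = support),
            class = "age_assignment")
}

#' @export
print.age_assignment <- function(x, ...) {
  cat("<age_assignment> status:", x$status,
      if (x$status == "dated") paste0("branch: ", x$branch,
                                      " (support ", x$presence_support, ")"),
      "\n")
  invisible(x)
}

#' Classify a gene's lineage from its ORF and locus ages
#'
#' Class I genes encode a protein only in the focal species (ORF dated to
#' the focal terminal branch); Class II genes encode a protein in the focal
#' species and its sister (ORF dated to the focal-sister ancestral branch).
#' The locus must be at least as old as the ORF (its branch ancestral to or
#' equal to the ORF branch); an ORF older than its locus is an impossible
#' history and is rejected.
#'
#' @param orf_age,locus_age `age_assignment` objects.
#' @param tree rooted `phylo` object.
#' @param focal,sister tip labels defining Class I (focal terminal branch)
#'   and Class II (focal+sister ancestral branch).
#' @return one of `"ClassI"`, `"ClassII"`, `"other"`, `"rejected"`, with a
#'   `reason` attribute when rejected.
#' @export
classify_lineage <- function(orf_age, locus_age, tree,
                             focal = "human", sister = "chimp") {
  if (orf_age$status != "dated" || locus_age$status != "dated") {
    out <- "rejected"
    attr(out, "reason") <- "undated input"
    return(out)
  }
  orf_leaves <- branch_leaves(orf_age$branch)
  locus_leaves <- branch_leaves(locus_age$branch)
  if (!all(orf_leaves %in% locus_leaves)) {
    out <- "rejected"
    attr(out, "reason") <- "ORF older than locus"
    return(out)
  }
  if (orf_age$branch == branch_id(focal)) return("ClassI")
  if (orf_age$branch == branch_id(c(focal, sister))) return("ClassII")
  "other"
}

#' Read presence profiles from a TSV file
#'
#' Expects columns `gene`, `species`, `state`.
#'
#' @param path TSV path.
#' @param entity passed to [presence_profile()].
#' @return named list of `presence_profile` objects, one per gene.
#' @export
read_presence_tsv <- function(path, entity = "orf") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "species", "state") %in% names(d)))
  lapply(split(d, d$gene), function(g)
    presence_profile(stats::setNames(g$state, g$species), entity = entity))
}
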