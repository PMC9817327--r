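ARMS <- c("soc", "txa")
LEVELS <- c("primary", "secondary", "tertiary")

# --- node constructors -------------------------------------------------------

chance_node <- function(label, branches) {
  structure(list(kind = "chance", label = label, branches = branches),
            class = "txa_node")
}

decision_node <- function(label, branches) {
  structure(list(kind = "decision", label = label, branches = branches),
            class = "txa_node")
}

terminal_node <- function(state) {
  stopifnot(state %in% c("alive", "dead"))
  structure(list(kind = "terminal", label = state, terminal_state = state),
            class = "txa_node")
}

branch <- function(label, prob, child, tags = list()) {
  list(label = label, prob = prob, child = child, tags = tags)
}

complement <- function(expr) paste0("1 - (", expr, ")")

# Death-probability expression for a pathway, by arm, ICU status, bleeding
# control status and mortality-allocation scheme.
death_expr <- function(arm, icu, uncontrolled, scheme) {
  all_cause <- if (arm == "txa") "rr_death_all_txa * p_death_all_soc" else
    "p_death_all_soc"
  bleed <- if (arm == "txa") "rr_death_bleed_txa * p_death_bleed_soc" else
    "p_death_bleed_soc"
  extra <- switch(scheme,
    additive_icu = if (icu) bleed else NULL,
    additive_uncontrolled = if (uncontrolled) bleed else NULL,
    residual_uniform = {
      all_cause <- paste0("(", all_cause, " - ", bleed, ")")
      if (uncontrolled) bleed else NULL
    })
  e <- if (is.null(extra)) all_cause else paste(all_cause, "+", extra)
  paste0("pmin(1, pmax(0, ", e, "))")
}

# Terminal survival split appended to every clinical pathway.
survival_split <- function(arm, icu, uncontrolled, scheme) {
  de <- death_expr(arm, icu, uncontrolled, scheme)
  chance_node("survival", list(
    branch("dead", de, terminal_node("dead")),
    branch("alive", complement(de), terminal_node("alive"))))
}

# ICU admission split followed by the survival split.  `uncontrolled` marks
# pathways where bleeding was not controlled by conservative measures.
icu_split <- function(arm, uncontrolled, scheme) {
  p_icu <- if (uncontrolled) "p_icu_uncontrolled" else "p_icu_controlled"
  chance_node("icu_admission", list(
    branch("icu", p_icu,
           survival_split(arm, TRUE, uncontrolled, scheme),
           tags = list(icu = TRUE)),
    branch("no_icu", complement(p_icu),
           survival_split(arm, FALSE, uncontrolled, scheme))))
}

# Surgical escalation for uncontrolled bleeding after failed conservative
# management: direct hysterectomy or devascularization with possible
# subsequent hysterectomy.
surgery_subtree <- function(arm, scheme, direct_hyst = TRUE) {
  after_devasc <- chance_node("after_devascularization", list(
    branch("hysterectomy", "p_hyst_after_devasc",
           icu_split(arm, TRUE, scheme), tags = list(hyst = TRUE)),
    branch("controlled", complement("p_hyst_after_devasc"),
           icu_split(arm, TRUE, scheme))))
  devasc <- branch("devascularization",
                   if (direct_hyst) complement("p_direct_hyst") else "1",
                   after_devasc, tags = list(devasc = TRUE))
  if (!direct_hyst) return(chance_node("surgery", list(devasc)))
  chance_node("surgery", list(
    branch("direct_hysterectomy", "p_direct_hyst",
           icu_split(arm, TRUE, scheme), tags = list(hyst = TRUE)),
    devasc))
}

# Atonic PPH subtree at one facility level.
atonic_subtree <- function(arm, level, scheme) {
  gate <- if (arm == "txa") "p_further_txa" else "p_further_soc"
  p_ubt <- paste0("p_ubt_", level)
  ubt_fail <- branch("ubt_failed", complement("p_ubt_effective"),
                     surgery_subtree(arm, scheme, direct_hyst = TRUE),
                     tags = list(ubt_fail = TRUE, uncontrolled = TRUE))
  ubt <- chance_node("ubt_outcome", list(
    branch("ubt_controlled", "p_ubt_effective",
           icu_split(arm, FALSE, scheme),
           tags = list(control = "conservative")),
    ubt_fail))
  further <- chance_node("ubt_insertion", list(
    branch("ubt", p_ubt, ubt, tags = list(ubt = TRUE)),
    branch("conservative_medical", complement(p_ubt),
           icu_split(arm, FALSE, scheme),
           tags = list(control = "conservative"))))
  chance_node("medical_management", list(
    branch("further_intervention", gate, further,
           tags = list(further = TRUE)),
    branch("controlled_medically", complement(gate),
           icu_split(arm, FALSE, scheme),
           tags = list(control = "medical"))))
}

# Traumatic PPH subtree: exploration and local repair, surgical escalation on
# failure.  With `gated = TRUE` the arm-specific further-intervention risk
# gates entry to local repair; otherwise all traumatic cases are explored.
traumatic_subtree <- function(arm, level, scheme, gated) {
  local <- chance_node("local_repair", list(
    branch("controlled_locally", "p_trauma_local_control",
           icu_split(arm, FALSE, scheme),
           tags = list(control = "conservative", local_repair = TRUE)),
    branch("repair_failed", complement("p_trauma_local_control"),
           surgery_subtree(arm, scheme, direct_hyst = FALSE),
           tags = list(local_repair = TRUE, uncontrolled = TRUE))))
  if (!gated) return(local)
  gate <- if (arm == "txa") "p_further_txa" else "p_further_soc"
  chance_node("medical_management", list(
    branch("further_intervention", gate, local, tags = list(further = TRUE)),
    branch("controlled_medically", complement(gate),
           icu_split(arm, FALSE, scheme),
           tags = list(control = "medical"))))
}

arm_subtree <- function(arm, structure) {
  scheme <- structure$mortality
  level_branches <- lapply(LEVELS, function(level) {
    pph <- chance_node("pph_type", list(
      branch("atonic", "p_atonic",
             atonic_subtree(arm, level, scheme),
             tags = list(pph_type = "atonic")),
      branch("traumatic", complement("p_atonic"),
             traumatic_subtree(arm, level, scheme, structure$traumatic_gated),
             tags = list(pph_type = "traumatic"))))
    branch(level, paste0("share_", level), pph, tags = list(level = level))
  })
  chance_node("facility_level", level_branches)
}

#' Build the two-arm PPH decision tree
#'
#' Constructs the decision tree comparing standard care (SOC) with TXA added
#' to standard care.  Both arms share an identical topology over facility
#' level (primary/secondary/tertiary) and PPH type (atonic/traumatic); the
#' arms differ only in the further-intervention risk and the two mortality
#' relative risks, plus the medical-management cost package attached later by
#' the payoff stage.  Branch probabilities are stored as symbolic expressions
#' over parameter names (plus `share_primary`/`share_secondary`/
#' `share_tertiary` from the facility mix) and evaluated on demand, so the
#' same tree serves the deterministic base case, one-way variation and
#' vectorized probabilistic draws.
#'
#' @param params A `txa_parameter_set` from [load_parameters()].
#' @param config An [analysis_config()]; supplies the facility mix and
#'   structural switches.
#' @return A `txa_tree` (root decision node plus evaluation context).
#' @export
build_base_tree <- function(params, config = analysis_config()) {
  stopifnot(inherits(params, "txa_parameter_set"),
            inherits(config, "txa_config"))
  root <- decision_node("strategy", list(
    branch("soc", "1", arm_subtree("soc", config$structure),
           tags = list(arm = "soc")),
    branch("txa", "1", arm_subtree("txa", config$structure),
           tags = list(arm = "txa"))))
  tree <- structure(list(root = root, params = params, config = config),
                    class = "txa_tree")
  refs <- setdiff(tree_parameter_refs(root), names(model_values(tree)))
  if (length(refs))
    stop("tree references missing parameters: ", paste(refs, collapse = ", "))
  tree
}

#' Evaluation environment for tree expressions
#'
#' Parameter base values plus the facility-mix shares.  Any entry may be
#' overridden (scalar or vector) to evaluate the tree elsewhere.
#' @param tree A `txa_tree` (or `params` plus `config`).
#' @param overrides Named list of replacement values.
#' @export
model_values <- function(tree, overrides = list()) {
  vals <- base_values(tree$params)
  mix <- tree$config$facility_mix
  vals$share_primary <- unname(mix[["primary"]])
  vals$share_secondary <- unname(mix[["secondary"]])
  vals$share_tertiary <- unname(mix[["tertiary"]])
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  vals
}

eval_expr <- function(expr, values) {
  eval(parse(text = expr)[[1]], envir = values, enclos = baseenv())
}

tree_parameter_refs <- function(node) {
  refs <- character()
  walk <- function(n) {
    if (n$kind == "terminal") return(invisible())
    for (b in n$branches) {
      v <- all.vars(parse(text = b$prob)[[1]])
      refs <<- union(refs, v)
      walk(b$child)
    }
  }
  walk(node)
  setdiff(refs, c("pmin", "pmax"))
}

default_tags <- function() {
  list(arm = NA_character_, level = NA_character_, pph_type = NA_character_,
       further = FALSE, ubt = FALSE, ubt_fail = FALSE, devasc = FALSE,
       hyst = FALSE, icu = FALSE, local_repair = FALSE, uncontrolled = FALSE,
       control = NA_character_)
}

#' Enumerate root-to-terminal pathways
#'
#' Depth-first enumeration in declared branch order.  Each pathway carries its
#' arm, facility level, PPH type, clinical event flags, terminal state, the
#' symbolic probability expression (product of branch expressions) and the
#' human-readable event sequence.
#'
#' @param tree A `txa_tree`.
#' @param arm `"soc"`, `"txa"` or `"both"`.
#' @param values Optional evaluation values (default: base case) used to add
#'   an evaluated `prob` column.
#' @return A data frame, one row per pathway, with class `txa_pathways`.
#' @export
enumerate_pathways <- function(tree, arm = "both",
                               values = model_values(tree)) {
  stopifnot(inherits(tree, "txa_tree"))
  arm <- match.arg(arm, c("both", ARMS))
  rows <- list()
  walk <- function(node, exprs, tags, seq) {
    if (node$kind == "terminal") {
      tags$terminal_state <- node$terminal_state
      tags$prob_expr <- paste(exprs, collapse = " * ")
      tags$event_sequence <- paste(seq, collapse = " > ")
      rows[[length(rows) + 1L]] <<- tags
      return(invisible())
    }
    for (b in node$branches) {
      t2 <- tags
      for (nm in names(b$tags)) t2[[nm]] <- b$tags[[nm]]
      walk(b$child, c(exprs, paste0("(", b$prob, ")")), t2, c(seq, b$label))
    }
  }
  for (ab in tree$root$branches) {
    if (arm != "both" && ab$tags$arm != arm) next
    tags <- default_tags()
    tags$arm <- ab$tags$arm
    walk(ab$child, character(), tags, character())
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df$pathway_id <- paste0(df$arm, "_",
                          stats::ave(seq_along(df$arm), df$arm,
                                     FUN = seq_along))
  df$prob <- vapply(df$prob_expr, function(e) {
    v <- eval_expr(e, values)
    if (length(v) != 1) NA_real_ else v
  }, numeric(1), USE.NAMES = FALSE)
  class(df) <- c("txa_pathways", "data.frame")
  df
}

#' Evaluate pathway probabilities at given parameter values
#'
#' Vector-valued entries in `values` (e.g. probabilistic draws) give a
#' pathways-by-draws matrix.
#'
#' @param pathways A `txa_pathways` frame.
#' @param values Evaluation environment from [model_values()].
#' @return Matrix with one row per pathway.
#' @export
pathway_prob_matrix <- function(pathways, values) {
  n <- max(vapply(values, length, integer(1)))
  m <- vapply(pathways$prob_expr, function(e) {
    v <- eval_expr(e, values)
    rep_len(v, n)
  }, numeric(n))
  if (n == 1L) matrix(m, ncol = 1L) else t(m)
}

#' Validate a decision tree
#'
#' Checks, at the supplied parameter values, that every chance-node branch
#' probability lies in `[0, 1]` and that branch probabilities sum to one
#' within tolerance; reports dangling parameter references and zero-mass
#' (unreachable) branches.
#'
#' @param tree A `txa_tree`.
#' @param values Evaluation values (default base case).
#' @param tol Probability-sum tolerance.
#' @return List with `ok` flag, `node_report` data frame, `dangling_refs`,
#'   `unreachable` labels.
#' @export
validate_tree <- function(tree, values = model_values(tree), tol = 1e-9) {
  reports <- list()
  unreachable <- character()
  walk <- function(node, path) {
    if (node$kind == "terminal") return(invisible())
    probs <- vapply(node$branches, function(b) {
      v <- eval_expr(b$prob, values)
      mean(v)  # scalar at base case
    }, numeric(1))
    if (node$kind == "chance") {
      reports[[length(reports) + 1L]] <<- data.frame(
        node = paste(path, node$label, sep = "/"),
        sum = sum(probs),
        min = min(probs), max = max(probs),
        ok = abs(sum(probs) - 1) <= tol && all(probs >= -tol) &&
          all(probs <= 1 + tol),
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(node$branches)) {
      b <- node$branches[[i]]
      if (probs[i] == 0)
        unreachable <<- c(unreachable,
                          paste(path, node$label, b$label, sep = "/"))
      walk(b$child, paste(path, node$label, b$label, sep = "/"))
    }
  }
  for (ab in tree$root$branches) walk(ab$child, ab$label)
  node_report <- do.call(rbind, reports)
  dangling <- setdiff(tree_parameter_refs(tree$root), names(values))
  list(ok = all(node_report$ok) && length(dangling) == 0,
       node_report = node_report,
       dangling_refs = dangling,
       unreachable = unreachable)
}

#' Export the tree as a nested list (for inspection/diffing)
#'
#' @param tree A `txa_tree`.
#' @return A nested list mirroring the node structure (version-tagged);
#'   serialize with [jsonlite::toJSON()] for a canonical text form.
#' @export
tree_as_list <- function(tree) {
  strip <- function(n) {
    if (n$kind == "terminal")
      return(list(kind = n$kind, state = n$terminal_state))
    list(kind = n$kind, label = n$label,
         branches = lapply(n$branches, function(b)
           list(label = b$label, prob = b$prob, child = strip(b$child))))
  }
  list(format_version = "1.0", root = strip(tree$root))
}
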