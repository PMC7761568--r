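## Plain-text model dialect: BoolNet-style "targets, factors" lines with '#'
## comments. A trailing "# kind: input|internal|phenotype" annotation on a
## rule line overrides the inferred node kind (identity rule => input,
## otherwise internal).

#' Read a Boolean network from a targets/factors model file
#'
#' @param path Path to the model file.
#' @return A validated [BooleanNetwork][BooleanNetwork-class].
#' @section Format:
#' One rule per line, `target, factors`, e.g. `TCR, Antigens & LCK_FYN &
#' !SHP`. Lines starting with `#` and an optional `targets, factors` header
#' are ignored; a trailing `# kind: phenotype` annotates the node role.
#' @seealso [writeBoolNet()]
#' @export
readBoolNet <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rules <- character()
  kinds <- character()
  seenAt <- integer()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^targets\\s*,\\s*factors\\s*$", line, ignore.case = TRUE)) next
    kind <- NA_character_
    if (grepl("#", line, fixed = TRUE)) {
      comment <- sub("^[^#]*#", "", line)
      m <- regmatches(comment,
                      regexpr("kind:\\s*(input|internal|phenotype)", comment))
      if (length(m) && nzchar(m))
        kind <- sub("kind:\\s*", "", m)
      line <- trimws(sub("#.*$", "", line))
    }
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0)
      stop(sprintf("line %d: expected 'target, factors' but found \"%s\"",
                   i, line), call. = FALSE)
    target <- trimws(substr(line, 1L, comma - 1L))
    factors <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", target))
      stop(sprintf("line %d: invalid target name \"%s\"", i, target),
           call. = FALSE)
    if (target %in% names(rules))
      stop(sprintf("line %d: duplicate target '%s' (first declared on line %d)",
                   i, target, seenAt[[target]]), call. = FALSE)
    expr <- tryCatch(parseRule(factors), error = function(e)
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE))
    rules[[target]] <- renderRule(expr)
    kinds[[target]] <- kind
    seenAt[[target]] <- i
  }
  if (!length(rules)) stop("model file declares no rules", call. = FALSE)
  net <- booleanNetwork(rules,
                        phenotypes = names(kinds)[!is.na(kinds) &
                                                  kinds == "phenotype"])
  ## explicit annotations override the inferred kinds
  explicit <- names(kinds)[!is.na(kinds)]
  net@kind[explicit] <- kinds[explicit]
  report <- validateNetwork(net)
  hard <- report[report$finding %in% c("undeclared_regulator", "duplicate_name"), ]
  if (nrow(hard))
    stop(paste(c("invalid model:", hard$message), collapse = "\n  "),
         call. = FALSE)
  if (nrow(report))
    warning(paste(report$message, collapse = "; "), call. = FALSE)
  net
}

#' Write a Boolean network as a targets/factors model file
#'
#' Nodes are written in declaration order so files diff stably;
#' `readBoolNet(writeBoolNet(net, path))` reproduces a network with
#' identical node set and per-node truth tables.
#'
#' @param net A [BooleanNetwork][BooleanNetwork-class].
#' @param path Output path.
#' @param comments Optional named character vector of per-node comments
#'   appended after the kind annotation.
#' @return `path`, invisibly.
#' @export
writeBoolNet <- function(net, path, comments = NULL) {
  lines <- c("targets, factors")
  for (nm in net@nodes) {
    extra <- if (!is.null(comments) && nm %in% names(comments))
      paste0(" ", comments[[nm]]) else ""
    lines <- c(lines, sprintf("%s, %s # kind: %s%s", nm,
                              renderRule(net@rules[[nm]]), net@kind[[nm]],
                              extra))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario configuration
#'
#' Parses a YAML scenario file into a cell condition, a list of
#' perturbations and a simulation configuration. Unspecified simulation
#' parameters take the documented defaults of [simulationConfig()].
#'
#' @param path Path to the YAML configuration.
#' @param net Network against which node names are validated (default: the
#'   built-in T-cell model).
#' @return List with elements `condition`
#'   ([CellCondition][CellCondition-class]), `perturbations` (list of
#'   [Perturbation][Perturbation-class]) and `config`
#'   ([SimulationConfig][SimulationConfig-class]).
#' @section Format:
#' \preformatted{
#' condition: LN            # catalogue name, or a mapping with fields
#'                          # name/active_inputs/initial_active/
#'                          # not_expressed/cell_type/localization
#' treatments: [anti-PD1]   # anti-X forces node X to 0
#' perturbations:           # explicit forcings
#'   LAG3: 1
#' simulation:
#'   n_trajectories: 10000
#'   t_max: 50
#'   seed: 1
#'   grid_points: 100
#'   convergence_window: 0.2
#' }
#' @export
#' @importFrom yaml read_yaml
readScenarioConfig <- function(path, net = buildTCellNetwork()) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)

  cond <- cfg$condition
  if (is.null(cond)) stop("config must name a condition", call. = FALSE)
  if (is.character(cond) && length(cond) == 1L) {
    catalogue <- tcellConditions()
    if (!cond %in% names(catalogue))
      stop(sprintf("unknown condition '%s'; known: %s", cond,
                   paste(names(catalogue), collapse = ", ")), call. = FALSE)
    condition <- catalogue[[cond]]
  } else {
    condition <- cellCondition(
      name = cond$name %||% "custom",
      activeInputs = as.character(cond$active_inputs %||% character()),
      initialActive = as.character(cond$initial_active %||% character()),
      notExpressed = as.character(cond$not_expressed %||% character()),
      cellType = cond$cell_type %||% "generic",
      localization = cond$localization %||% "none")
  }
  badNodes <- setdiff(c(condition@activeInputs, condition@initialActive,
                        condition@notExpressed), net@nodes)
  if (length(badNodes))
    stop(sprintf("condition references unknown node(s): %s",
                 paste(badNodes, collapse = ", ")), call. = FALSE)

  perts <- list()
  if (!is.null(cfg$treatments))
    perts <- c(perts, treatmentPerturbations(unlist(cfg$treatments)))
  if (!is.null(cfg$perturbations)) {
    for (nm in names(cfg$perturbations))
      perts <- c(perts, perturbation(nm, cfg$perturbations[[nm]]))
  }
  badP <- setdiff(vapply(perts, function(p) p@node, ""), net@nodes)
  if (length(badP))
    stop(sprintf("perturbation on unknown node(s): %s",
                 paste(badP, collapse = ", ")), call. = FALSE)
  pn <- vapply(perts, function(p) p@node, "")
  pv <- vapply(perts, function(p) p@value, 0L)
  for (nm in unique(pn[duplicated(pn)])) {
    if (length(unique(pv[pn == nm])) > 1L)
      stop(sprintf("conflicting perturbations on node '%s'", nm),
           call. = FALSE)
  }
  perts <- perts[!duplicated(pn)]

  sim <- cfg$simulation %||% list()
  config <- simulationConfig(
    nTrajectories = sim$n_trajectories %||% 10000L,
    tMax = sim$t_max %||% 50,
    seed = sim$seed %||% 1L,
    gridPoints = sim$grid_points %||% 100L,
    convergenceWindow = sim$convergence_window %||% 0.2,
    convergenceTol = sim$convergence_tol %||% 0.02)

  list(condition = condition, perturbations = perts, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
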