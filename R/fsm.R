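#' Finite-state automata of the agent types
#'
#' Each agent type follows a finite state machine; an agent follows at most
#' one edge per tick.  `agent_fsms()` returns the declared state inventory
#' and edge set per type — the behavioural contract the simulation engine is
#' held to by [validate_trace()].  The tables can be written to (and read
#' back from) plain text, one file per agent type, so tests can pin exact
#' machines.
#'
#' @return a named list (one entry per agent type) of
#'   `list(states = character, edges = data.frame(from, to, trigger))`.
#' @examples
#' fsm <- agent_fsms()
#' fsm$Parenchymal$edges
#' @export
agent_fsms <- function() {
  E <- function(...) {
    v <- c(...)
    if (length(v) == 0L)
      return(data.frame(from = character(0), to = character(0),
                        trigger = character(0), stringsAsFactors = FALSE))
    m <- matrix(v, ncol = 3, byrow = TRUE)
    data.frame(from = m[, 1], to = m[, 2], trigger = m[, 3],
               stringsAsFactors = FALSE)
  }
  list(
    Parenchymal = list(
      states = c("PC_Healthy", "PC_Stressed", "PC_Infected",
                 "PC_DeadNecrotic", "PC_DeadApoptotic"),
      edges = E(
        "PC_Healthy", "PC_Infected", "virus_threshold",
        "PC_Healthy", "PC_Stressed", "adjacent_infected",
        "PC_Stressed", "PC_Infected", "virus_threshold",
        "PC_Stressed", "PC_Healthy", "stress_recovered",
        "PC_Stressed", "PC_DeadApoptotic", "killed_nk",
        "PC_Infected", "PC_DeadNecrotic", "viral_lysis",
        "PC_Infected", "PC_DeadNecrotic", "killed_gran",
        "PC_Infected", "PC_DeadApoptotic", "killed_nk",
        "PC_Infected", "PC_DeadApoptotic", "killed_ctl",
        "PC_Infected", "PC_DeadApoptotic", "killed_mac")),
    Portal = list(states = "Portal_Open", edges = E()),
    Dendritic = list(
      states = c("DC_Immature", "DC_Activated", "DC_Presenting",
                 "DC_DeadApoptotic"),
      edges = E(
        "DC_Immature", "DC_Activated", "activation_infected_pc",
        "DC_Immature", "DC_Activated", "activation_apoptotic_debris",
        "DC_Activated", "DC_Presenting", "arrived_zone2",
        "DC_Immature", "DC_DeadApoptotic", "lifespan",
        "DC_Activated", "DC_DeadApoptotic", "lifespan",
        "DC_Presenting", "DC_DeadApoptotic", "lifespan")),
    Macrophage = list(
      states = c("M_Resting", "M_M1", "M_M2", "M_DeadApoptotic"),
      edges = E(
        "M_Resting", "M_M1", "pk1_threshold",
        "M_M1", "M_M2", "resolution",
        "M_M2", "M_M1", "pk1_threshold",
        "M_Resting", "M_DeadApoptotic", "lifespan",
        "M_M1", "M_DeadApoptotic", "lifespan",
        "M_M2", "M_DeadApoptotic", "lifespan")),
    NaturalKiller = list(
      states = c("NK_Patrol", "NK_DeadApoptotic"),
      edges = E("NK_Patrol", "NK_DeadApoptotic", "lifespan")),
    Granulocyte = list(
      states = c("G_Resting", "G_Active", "G_DeadApoptotic"),
      edges = E(
        "G_Resting", "G_Active", "pk1_threshold",
        "G_Resting", "G_Active", "necrotic_contact",
        "G_Active", "G_DeadApoptotic", "burst_exhausted",
        "G_Resting", "G_DeadApoptotic", "lifespan",
        "G_Active", "G_DeadApoptotic", "lifespan")),
    TCell = list(
      states = c("T_Naive", "T_Activated", "T_Effector", "T_Memory",
                 "T_DeadApoptotic"),
      edges = E(
        "T_Naive", "T_Activated", "antigen_presented",
        "T_Activated", "T_Effector", "division_complete",
        "T_Activated", "T_Memory", "resolution",
        "T_Effector", "T_Memory", "resolution",
        "T_Naive", "T_DeadApoptotic", "lifespan",
        "T_Activated", "T_DeadApoptotic", "lifespan",
        "T_Effector", "T_DeadApoptotic", "lifespan",
        "T_Memory", "T_DeadApoptotic", "lifespan")),
    BCell = list(
      states = c("B_Naive", "B_Activated", "B_Plasma", "B_Memory",
                 "B_DeadApoptotic"),
      edges = E(
        "B_Naive", "B_Activated", "antigen_presented",
        "B_Activated", "B_Plasma", "tcell_help",
        "B_Activated", "B_Memory", "resolution",
        "B_Naive", "B_DeadApoptotic", "lifespan",
        "B_Activated", "B_DeadApoptotic", "lifespan",
        "B_Plasma", "B_DeadApoptotic", "lifespan",
        "B_Memory", "B_DeadApoptotic", "lifespan")),
    CTL = list(
      states = c("C_Naive", "C_Activated", "C_Effector", "C_Memory",
                 "C_DeadApoptotic"),
      edges = E(
        "C_Naive", "C_Activated", "antigen_presented",
        "C_Activated", "C_Effector", "division_complete",
        "C_Activated", "C_Memory", "resolution",
        "C_Effector", "C_Memory", "resolution",
        "C_Naive", "C_DeadApoptotic", "lifespan",
        "C_Activated", "C_DeadApoptotic", "lifespan",
        "C_Effector", "C_DeadApoptotic", "lifespan",
        "C_Memory", "C_DeadApoptotic", "lifespan"))
  )
}

#' @rdname agent_fsms
#' @param fsms as returned by [agent_fsms()].
#' @param dir directory for the per-type text files.
#' @export
write_fsms <- function(fsms = agent_fsms(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fsms)) {
    f <- fsms[[nm]]
    lines <- c("[states]", f$states, "[edges]",
               sprintf("%s -> %s : %s", f$edges$from, f$edges$to,
                       f$edges$trigger))
    writeLines(lines, file.path(dir, paste0(nm, ".fsm")))
  }
  invisible(dir)
}

#' @rdname agent_fsms
#' @export
read_fsms <- function(dir) {
  files <- list.files(dir, pattern = "\\.fsm$", full.names = TRUE)
  out <- list()
  for (f in files) {
    nm <- sub("\\.fsm$", "", basename(f))
    lines <- readLines(f)
    i1 <- which(lines == "[states]")
    i2 <- which(lines == "[edges]")
    states <- lines[seq.int(i1 + 1L, i2 - 1L)]
    el <- if (i2 >= length(lines)) character(0) else
      lines[seq.int(i2 + 1L, length(lines))]
    el <- el[nzchar(el)]
    m <- regmatches(el, regexec("^(\\S+) -> (\\S+) : (\\S+)$", el))
    out[[nm]] <- list(
      states = states,
      edges = data.frame(from = vapply(m, `[`, "", 2L),
                         to = vapply(m, `[`, "", 3L),
                         trigger = vapply(m, `[`, "", 4L),
                         stringsAsFactors = FALSE))
  }
  out[names(agent_fsms())[names(agent_fsms()) %in% names(out)]]
}

#' Validate a transition trace against the declared automata
#'
#' A trace records one row per state transition (tick, agent id, agent type,
#' from-state, to-state, trigger); runs produce one with `run(..., trace =
#' TRUE)`.  The validator checks that (i) every transition is a declared
#' edge of the agent's automaton, (ii) no agent follows more than one edge
#' in a tick, and (iii) each agent's transitions chain (the from-state of a
#' transition equals the to-state of the previous one).
#'
#' @param trace a data.frame as returned in `run(...)$trace`.
#' @param fsms declared automata, from [agent_fsms()] or [read_fsms()].
#' @return `list(valid = logical, violations = data.frame)`.
#' @export
validate_trace <- function(trace, fsms = agent_fsms()) {
  viol <- list()
  key <- function(t, f, to, tr) paste(t, f, to, tr, sep = "|")
  declared <- unlist(lapply(names(fsms), function(nm) {
    e <- fsms[[nm]]$edges
    if (nrow(e) == 0) character(0) else key(nm, e$from, e$to, e$trigger)
  }))
  k <- key(trace$agent_type, trace$from, trace$to, trace$trigger)
  bad <- !(k %in% declared)
  if (any(bad))
    viol$undeclared_edge <- trace[bad, , drop = FALSE]
  dup <- duplicated(trace[, c("agent_id", "tick")])
  if (any(dup))
    viol$multiple_edges_per_tick <- trace[dup, , drop = FALSE]
  o <- order(trace$agent_id, trace$tick)
  tr <- trace[o, ]
  same <- c(FALSE, tr$agent_id[-1] == tr$agent_id[-nrow(tr)])
  chainbad <- same & c(FALSE, tr$from[-1] != tr$to[-nrow(tr)])
  if (any(chainbad))
    viol$broken_chain <- tr[chainbad, , drop = FALSE]
  list(valid = length(viol) == 0L, violations = viol)
}
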