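# Angiogenesis sub-engine: sprout initiation along mature vessels, tip
# chemotaxis, anastomosis (all in compiled code: cpp_vasc_iter) and the
# perfusion update. Vessel geometry lives on the fine lattice; chains are
# stored as parallel vectors (parent vessel, origin, tip, closure state)
# with their occupied sites in `state$csites`.

empty_chains <- function() {
  list(parent = integer(0),
       origin = matrix(integer(0), ncol = 3),
       open = logical(0),
       closed_type = integer(0),  # 0 open, 1 fused to mature, 2 to chain
       closed_id = integer(0),
       perfused = logical(0),
       tip = matrix(integer(0), ncol = 3))
}

n_chains <- function(state) length(state$chains$parent)

# Shared driver for the three vasculature phases.
vasc_phase <- function(state, branch, migrate, anast) {
  cfg <- state$config
  ch <- state$chains
  cl <- state$cells
  res <- cpp_vasc_iter(
    state$msites, state$mline,
    state$csites$m, state$csites$chain,
    ch$parent, ch$origin, ch$open, ch$tip,
    cbind(cl$x, cl$y, cl$z), cl$hypoxic,
    cfg$tumor_lattice_n, cfg$vessel_lattice_n,
    coarse_um(cfg), fine_um(cfg),
    cfg$max_branch_prob, cfg$vegf_radius,
    max(1L, round(cfg$tip_speed / fine_um(cfg))),
    cfg$anastomosis_radius,
    branch, migrate, anast
  )
  b <- length(res$new_chain_parent)
  if (b > 0) {
    ch$parent <- c(ch$parent, res$new_chain_parent)
    ch$origin <- rbind(ch$origin, res$new_chain_origin)
    ch$closed_type <- c(ch$closed_type, rep(0L, b))
    ch$closed_id <- c(ch$closed_id, rep(NA_integer_, b))
    ch$perfused <- c(ch$perfused, rep(FALSE, b))
  }
  ch$tip <- res$tips
  ch$open <- res$open
  if (length(res$closed_chain) > 0) {
    idx <- res$closed_chain
    ch$closed_type[idx] <- res$closed_type + 1L  # 1 mature, 2 chain
    ch$closed_id[idx] <- res$closed_id
  }
  if (nrow(res$new_sites) > 0) {
    state$csites$m <- rbind(state$csites$m, res$new_sites)
    state$csites$chain <- c(state$csites$chain, res$new_site_chain)
  }
  state$chains <- ch
  state
}

#' Vessel sprouting
#'
#' Each mature-vessel fine-lattice site may initiate one sprout per
#' iteration with probability `max_branch_prob * (1 - d_min / vegf_radius)`,
#' where `d_min` is the exact distance from that site to the nearest hypoxic
#' cell; sites farther than `vegf_radius` from all hypoxic cells never
#' branch. With no hypoxic cells anywhere, no sprouts form.
#'
#' @param state An `abm_state` with oxygenation classified.
#' @return The updated `abm_state`.
#' @export
vasc_branch <- function(state) vasc_phase(state, TRUE, FALSE, FALSE)

#' Sprout-tip migration
#'
#' Each open sprout tip advances `tip_speed` um along the discrete ray
#' toward the nearest cancer cell (ties broken by lowest
#' coordinate-lexicographic order); the visited fine-lattice sites are
#' appended behind the tip as stalk. Tips are stationary when no cancer
#' cells exist.
#'
#' @param state An `abm_state`.
#' @return The updated `abm_state`.
#' @export
vasc_migrate_tips <- function(state) vasc_phase(state, FALSE, TRUE, FALSE)

#' Anastomosis
#'
#' Any open sprout tip within `anastomosis_radius` of another sprout's tip
#' or stalk, or of a mature vessel, fuses with the nearest such site: the
#' chain closes and its tip is removed. A tip ignores its own chain and the
#' part of its parent vessel within `anastomosis_radius` of its own origin,
#' so a fresh sprout does not immediately fuse back at its branch point.
#'
#' @param state An `abm_state`.
#' @return The updated `abm_state`.
#' @export
vasc_anastomose <- function(state) vasc_phase(state, FALSE, FALSE, TRUE)

#' Perfusion update
#'
#' Mature vessels are always perfused. A sprout chain is perfused when it
#' is closed (a loop has been completed) and both of its attachment points
#' — its parent vessel and the object it fused with — connect to the mature
#' network through the graph of mature vessels and closed chains; open
#' chains carry no blood. Newly perfused chains extend the oxygenation mask
#' incrementally.
#'
#' @param state An `abm_state`.
#' @return The updated `abm_state`.
#' @export
update_perfusion <- function(state) {
  ch <- state$chains
  k <- length(ch$parent)
  if (k == 0) return(state)
  # Every chain's origin-end parent is a mature vessel here, so each closed
  # chain is anchored to the mature network through its own parent and the
  # general graph reachability of perfusion_flags() collapses to: closed,
  # and fused to a mature vessel or to another closed chain. (The tests
  # check this equivalence against the full graph computation.)
  closed <- ch$closed_type > 0L
  flags <- closed & (ch$closed_type == 1L |
                       (ch$closed_type == 2L & closed[pmax(ch$closed_id, 1L)]))
  newly <- which(flags & !ch$perfused)
  ch$perfused <- ch$perfused | flags
  state$chains <- ch
  if (length(newly) > 0) {
    sel <- state$csites$chain %in% newly
    state$oxy <- oxy_mask(state$csites$m[sel, , drop = FALSE], state$config,
                          base = state$oxy)
  }
  state
}

#' Perfusion flags for a chain-attachment graph
#'
#' Pure graph computation behind [update_perfusion()], exposed for testing
#' and for analysing vessel networks outside a simulation. Chain `i`
#' attaches at one end to `parent` (a mature vessel or another chain) and,
#' if `closed[i]`, at the other end to the object described by
#' `closed_to_*`. A chain is perfused when it is closed and each of its two
#' attachment objects reaches the mature network in the undirected graph
#' whose vertices are mature vessels plus closed chains and whose edges
#' join each closed chain to its attachment objects.
#'
#' @param parent_type,parent_id Attachment object at the chain origin
#'   (`"mature"` or `"chain"` plus an id).
#' @param closed Logical; is the chain closed (fused at the tip end)?
#' @param closed_to_type,closed_to_id Attachment object at the tip end
#'   (`NA` for open chains).
#' @return Logical vector: perfusion flag per chain.
#' @export
perfusion_flags <- function(parent_type, parent_id, closed,
                            closed_to_type, closed_to_id) {
  k <- length(closed)
  if (k == 0) return(logical(0))
  # vertex labels: "M" = merged mature network, "C<i>" = closed chain i
  closed_idx <- which(closed)
  vname <- function(type, id) {
    if (is.na(type)) return(NA_character_)
    if (type == "mature") return("M")
    if (id %in% closed_idx) paste0("C", id) else NA_character_
  }
  adj <- list(M = character(0))
  for (i in closed_idx) adj[[paste0("C", i)]] <- character(0)
  for (i in closed_idx) {
    me <- paste0("C", i)
    for (other in list(vname(parent_type[i], parent_id[i]),
                       vname(closed_to_type[i], closed_to_id[i]))) {
      if (!is.na(other)) {
        adj[[me]] <- c(adj[[me]], other)
        adj[[other]] <- c(adj[[other]], me)
      }
    }
  }
  reach <- setNames(rep(FALSE, length(adj)), names(adj))
  queue <- "M"
  reach["M"] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- unique(adj[[v]])
    new <- nb[!reach[nb]]
    reach[new] <- TRUE
    queue <- c(queue, new)
  }
  anchored <- function(type, id) {
    v <- vname(type, id)
    !is.na(v) && isTRUE(unname(reach[v]))
  }
  out <- logical(k)
  for (i in closed_idx) {
    out[i] <- anchored(parent_type[i], parent_id[i]) &&
      anchored(closed_to_type[i], closed_to_id[i])
  }
  out
}
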