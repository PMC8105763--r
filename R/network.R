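#' Trust matrix governing directed site-to-site transfers
#'
#' A permission table owned by the analysis center: it prespecifies which
#' directed site-to-site file transfers are allowed. Transfers to or from the
#' analysis center are always allowed; site-to-site pairs are denied by
#' default until the center enables them. Only the center may mutate the
#' matrix, and any transfer violating it terminates the analysis run.
#'
#' @param sites site identifiers.
#' @param center analysis-center identifier.
#' @param allow optional list of `c(from, to)` site pairs to permit.
#' @return an object of class `trust_matrix` (`allowed` logical matrix,
#'   `owner`, `version`).
#' @export
trust_matrix <- function(sites, center = "center", allow = list()) {
  parties <- c(center, sites)
  if (anyDuplicated(parties))
    vdra_error("vdra_config_error", "duplicate party identifiers")
  allowed <- matrix(FALSE, length(parties), length(parties),
                    dimnames = list(parties, parties))
  allowed[center, ] <- TRUE   # center <-> site always allowed
  allowed[, center] <- TRUE
  diag(allowed) <- FALSE
  for (pr in allow) allowed[pr[1L], pr[2L]] <- TRUE
  structure(list(allowed = allowed, owner = center, version = 1L),
            class = "trust_matrix")
}

#' Create a simulated file-transfer network
#'
#' Models the transfer fabric of a distributed data network: one mailbox
#' directory pair (inbox/outbox) per party under a versioned run directory,
#' an append-only audit log on a deterministic logical clock, per-leg
#' transfer metrics, and the center-owned trust matrix. Re-creating a
#' network over an existing root starts a fresh versioned run directory and
#' preserves prior audit trails.
#'
#' @param root directory under which run directories are created.
#' @param sites site identifiers (at least 2).
#' @param center analysis-center identifier.
#' @param routing `"direct"` (site-to-site transfers travel one leg) or
#'   `"hub_and_spoke"` (site-to-site exchanges are relayed through the
#'   center, two legs per exchange — the legacy workflow).
#' @param trust a [trust_matrix()]; default denies all site-to-site pairs.
#' @param batch_transfers logical; multi-file manifests delivered atomically.
#' @return an object of class `vdra_network` (environment).
#' @export
create_network <- function(root, sites, center = "center",
                           routing = c("direct", "hub_and_spoke"),
                           trust = NULL, batch_transfers = TRUE) {
  routing <- match.arg(routing)
  if (length(sites) < 1L)
    vdra_error("vdra_config_error", "a network needs at least one site")
  parties <- c(center, sites)
  if (anyDuplicated(parties))
    vdra_error("vdra_config_error", "duplicate party identifiers")
  trust <- trust %||% trust_matrix(sites, center)
  if (!identical(sort(rownames(trust$allowed)), sort(parties)))
    vdra_error("vdra_config_error", "trust matrix parties do not match network")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  prior <- list.files(root, pattern = "^run-\\d+$")
  run_dir <- file.path(root, sprintf("run-%03d", length(prior) + 1L))
  for (p in parties) {
    dir.create(file.path(run_dir, p, "inbox"), recursive = TRUE)
    dir.create(file.path(run_dir, p, "outbox"), recursive = TRUE)
  }
  net <- new.env(parent = emptyenv())
  net$center <- center
  net$sites <- sites
  net$routing <- routing
  net$batch_transfers <- batch_transfers
  net$trust <- trust
  net$run_dir <- run_dir
  net$clock <- 0L
  net$terminated <- FALSE
  net$audit <- list()
  net$legs <- 0L
  net$manifest_count <- 0L
  net$bytes <- 0
  net$party_bytes <- setNames(numeric(length(parties)), parties)
  net$max_payload_dim <- c(0L, 0L)
  net$site_exchanges <- 0L   # logical site<->site exchanges requested
  net$manifest_log <- list() # request_id -> manifest (for audits)
  class(net) <- "vdra_network"
  net
}

#' @export
print.vdra_network <- function(x, ...) {
  cat(sprintf("<vdra_network> center '%s' + %d site(s), %s routing, %s\n",
              x$center, length(x$sites), x$routing,
              if (x$terminated) "TERMINATED" else "active"))
  cat(sprintf("  run dir: %s\n  legs delivered: %d, bytes: %.0f\n",
              x$run_dir, x$legs, x$bytes))
  invisible(x)
}

center_id <- function(network) network$center
outbox <- function(network, party) file.path(network$run_dir, party, "outbox")
inbox <- function(network, party) file.path(network$run_dir, party, "inbox")

audit_event <- function(network, event, manifest = NULL, reason = NULL) {
  network$clock <- network$clock + 1L
  entry <- list(tick = network$clock, event = event,
                request_id = manifest$request_id %||% NA_character_,
                from = manifest$from %||% NA_character_,
                to = manifest$to %||% NA_character_,
                n_files = length(manifest$files %||% list()),
                reason = reason %||% NA_character_)
  network$audit[[length(network$audit) + 1L]] <- entry
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE),
      file = file.path(network$run_dir, "audit.jsonl"),
      sep = "\n", append = TRUE)
  invisible(entry)
}

#' Retrieve the audit log of a network
#'
#' @param network a `vdra_network`.
#' @return data.frame of audit entries (tick, event, request id, from, to,
#'   file count, reason), in logical-clock order.
#' @export
audit_log <- function(network) {
  if (!length(network$audit))
    return(data.frame(tick = integer(), event = character(),
                      request_id = character(), from = character(),
                      to = character(), n_files = integer(),
                      reason = character()))
  do.call(rbind, lapply(network$audit, function(e)
    data.frame(tick = e$tick, event = e$event, request_id = e$request_id,
               from = e$from, to = e$to, n_files = e$n_files,
               reason = e$reason)))
}

#' Mutate the trust matrix (analysis center only)
#'
#' Applies a permission change if and only if the acting party is the
#' analysis center that owns the matrix; the version is incremented and the
#' change audited. A site attempting to (self-)authorize a transfer route
#' gets a permission error and no mutation.
#'
#' @param network a `vdra_network`.
#' @param from,to directed pair the permission applies to.
#' @param allowed logical.
#' @param actor the party requesting the change.
#' @return the updated `trust_matrix`, invisibly.
#' @export
set_trust <- function(network, from, to, allowed, actor) {
  if (!identical(actor, network$trust$owner)) {
    audit_event(network, "rejected",
                list(from = from, to = to),
                reason = sprintf("trust mutation denied for '%s'", actor))
    vdra_error("vdra_permission_error",
      "only the analysis center may modify the trust matrix")
  }
  if (!from %in% rownames(network$trust$allowed) ||
      !to %in% rownames(network$trust$allowed))
    vdra_error("vdra_routing_error", "unknown party in trust mutation")
  network$trust$allowed[from, to] <- isTRUE(allowed)
  network$trust$version <- network$trust$version + 1L
  audit_event(network, "trust-updated", list(from = from, to = to),
              reason = sprintf("allowed=%s version=%d", allowed,
                               network$trust$version))
  jsonlite::write_json(
    list(owner = network$trust$owner, version = network$trust$version,
         allowed = as.data.frame(network$trust$allowed)),
    file.path(network$run_dir, "trust.json"), auto_unbox = TRUE)
  invisible(network$trust)
}

new_manifest <- function(network, from, to, paths) {
  if (!length(paths)) vdra_error("vdra_manifest_error", "empty manifest")
  network$manifest_count <- network$manifest_count + 1L
  files <- lapply(paths, function(p) list(
    name = basename(p), byte_size = file.size(p), checksum = file_md5(p)))
  m <- list(request_id = sprintf("req-%05d", network$manifest_count),
            from = from, to = to, files = files,
            created_at = network$clock + 1L)
  network$manifest_log[[m$request_id]] <- m
  m
}

#' Scan mailboxes against the audit log (governance invariant)
#'
#' Verifies that every file present in any receiver's inbox arrived through
#' a trust-permitted, audited, delivered manifest.
#'
#' @param network a `vdra_network`.
#' @return list with `ok` (logical) and `orphans` (files with no delivering
#'   manifest).
#' @export
governance_scan <- function(network) {
  log <- audit_log(network)
  delivered <- log$request_id[log$event == "delivered"]
  orphans <- character(0)
  for (p in c(network$center, network$sites)) {
    have <- list.files(inbox(network, p))
    expected <- unlist(lapply(network$manifest_log[delivered], function(m)
      if (m$to == p) vapply(m$files, `[[`, character(1), "name")))
    orphans <- c(orphans, setdiff(have, expected))
  }
  list(ok = length(orphans) == 0L, orphans = orphans)
}

payload_dims <- function(path) {
  # sidecars carry payload dimensions; record the largest matrix moved
  if (!grepl("\\.json$", path)) return(NULL)
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta$nrow)) return(NULL)
  c(as.integer(meta$nrow), as.integer(meta$ncol))
}

#' Execute one transfer leg
#'
#' Moves a manifest's files from the sender's outbox to the receiver's
#' inbox. The manifest is delivered atomically (all files or none) after
#' checksum verification, and every event is audited. A transfer the trust
#' matrix forbids is rejected and terminates the entire analysis run; a
#' checksum failure merely rejects the manifest. Nothing is delivered on a
#' terminated network.
#'
#' @param network a `vdra_network`.
#' @param manifest a manifest from [route()] or `new_manifest`; alternatively
#'   pass `from`, `to`, `files` to build one.
#' @param from,to,files convenience arguments to build a manifest from file
#'   paths in the sender's outbox.
#' @return delivery receipt (list) invisibly.
#' @export
transfer <- function(network, manifest = NULL, from = NULL, to = NULL,
                     files = NULL) {
  if (is.null(manifest)) manifest <- new_manifest(network, from, to, files)
  if (network$terminated)
    vdra_error("vdra_termination_error",
      "analysis run is terminated; no further transfers are delivered")
  if (!length(manifest$files))
    vdra_error("vdra_manifest_error", "empty manifest")
  parties <- rownames(network$trust$allowed)
  if (!manifest$from %in% parties || !manifest$to %in% parties)
    vdra_error("vdra_routing_error", "unknown party on manifest")
  audit_event(network, "submitted", manifest)
  if (!network$trust$allowed[manifest$from, manifest$to]) {
    audit_event(network, "rejected", manifest, reason = "trust violation")
    network$terminated <- TRUE
    audit_event(network, "terminated", manifest,
                reason = sprintf("trust matrix forbids %s -> %s",
                                 manifest$from, manifest$to))
    vdra_error("vdra_termination_error", sprintf(
      "trust violation (%s -> %s): analysis terminated",
      manifest$from, manifest$to))
  }
  src <- file.path(outbox(network, manifest$from),
                   vapply(manifest$files, `[[`, character(1), "name"))
  ok <- file.exists(src)
  if (!all(ok))
    vdra_error("vdra_manifest_error", sprintf(
      "file(s) missing from outbox of '%s': %s", manifest$from,
      paste(basename(src[!ok]), collapse = ", ")))
  sums <- vapply(src, file_md5, character(1))
  declared <- vapply(manifest$files, `[[`, character(1), "checksum")
  if (!identical(unname(sums), unname(declared))) {
    audit_event(network, "rejected", manifest, reason = "checksum mismatch")
    vdra_error("vdra_integrity_error",
      "checksum mismatch on delivery; manifest rejected")
  }
  # atomic batch: verify everything first, then place all files
  dst <- file.path(inbox(network, manifest$to), basename(src))
  file.copy(src, dst, overwrite = TRUE)
  bytes <- sum(file.size(dst))
  network$legs <- network$legs + 1L
  network$bytes <- network$bytes + bytes
  network$party_bytes[manifest$from] <- network$party_bytes[manifest$from] + bytes
  for (p in src) {
    d <- payload_dims(p)
    if (!is.null(d) && prod(d) > prod(network$max_payload_dim))
      network$max_payload_dim <- d
  }
  audit_event(network, "delivered", manifest)
  invisible(list(request_id = manifest$request_id, delivered = TRUE,
                 n_files = length(manifest$files), bytes = bytes))
}

#' Route files between parties under the network's routing mode
#'
#' Direct mode sends a site-to-site batch in one leg. Hub-and-spoke mode —
#' the legacy workflow in which sites may only talk to the analysis center —
#' expands a site-to-site request into two legs (sender to center, center to
#' receiver), doubling the transfer count for every site-to-site exchange.
#' Transfers involving the center are always a single leg.
#'
#' @param network a `vdra_network`.
#' @param from,to party identifiers.
#' @param files paths of files sitting in the sender's outbox.
#' @return list of the manifests delivered (one per leg).
#' @export
route <- function(network, from, to, files) {
  parties <- c(network$center, network$sites)
  if (!from %in% parties || !to %in% parties)
    vdra_error("vdra_routing_error", sprintf("unknown party '%s'",
               setdiff(c(from, to), parties)[1L]))
  site_to_site <- from != network$center && to != network$center
  if (site_to_site) network$site_exchanges <- network$site_exchanges + 1L
  if (site_to_site && network$routing == "hub_and_spoke") {
    m1 <- new_manifest(network, from, network$center, files)
    transfer(network, m1)
    # center relays: files move from its inbox to its outbox, then onward
    relay <- file.path(outbox(network, network$center),
                       vapply(files, basename, character(1)))
    file.copy(file.path(inbox(network, network$center), basename(relay)),
              relay, overwrite = TRUE)
    m2 <- new_manifest(network, network$center, to, relay)
    transfer(network, m2)
    list(m1, m2)
  } else {
    m <- new_manifest(network, from, to, files)
    transfer(network, m)
    list(m)
  }
}

# write a numeric vector/matrix into a party's outbox and route it onward
send_vector <- function(network, from, to, x, name, kind) {
  files <- write_payload(as.matrix(x), outbox(network, from), name, from, kind)
  route(network, from, to, files)
}

# send a gram block (small p_i x p_j CSV + sidecar) to another party
send_block <- function(network, from, to, block, name) {
  files <- write_payload(block$block, outbox(network, from), name, from,
                         "gram-block",
                         extra = list(site_i = block$site_i,
                                      site_j = block$site_j,
                                      n_rows = block$n_rows))
  route(network, from, to, files)
}

#' Transfer metrics of a network run
#'
#' @param network a `vdra_network`.
#' @return list with delivered legs, manifest count, total and per-party
#'   bytes, the largest payload dimension moved, and the number of logical
#'   site-to-site exchanges requested.
#' @export
transfer_metrics <- function(network) {
  list(legs = network$legs, manifests = network$manifest_count,
       bytes = network$bytes, party_bytes = as.list(network$party_bytes),
       max_payload_dim = network$max_payload_dim,
       site_exchanges = network$site_exchanges,
       terminated = network$terminated)
}

#' Compare transfer metrics between two runs
#'
#' Side-by-side accounting for two runs of the same analysis under different
#' routing modes: legs, bytes, and largest payload dimension, with a note on
#' which quantities scale with the cohort size n (masked-column payloads)
#' versus the model size p (Gram blocks).
#'
#' @param metrics_a,metrics_b outputs of [transfer_metrics()].
#' @param labels names for the two runs.
#' @return a data.frame, one row per metric.
#' @export
report_metrics <- function(metrics_a, metrics_b,
                           labels = c("run_a", "run_b")) {
  row <- function(metric, a, b, scales_with)
    data.frame(metric = metric, a = a, b = b, scales_with = scales_with)
  out <- rbind(
    row("transfer legs", metrics_a$legs, metrics_b$legs, "exchanges"),
    row("manifests", metrics_a$manifests, metrics_b$manifests, "exchanges"),
    row("total bytes", metrics_a$bytes, metrics_b$bytes, "n (mask payloads)"),
    row("max payload rows", metrics_a$max_payload_dim[1L],
        metrics_b$max_payload_dim[1L], "n"),
    row("max payload cols", metrics_a$max_payload_dim[2L],
        metrics_b$max_payload_dim[2L], "mask dimension g"),
    row("site-site exchanges", metrics_a$site_exchanges,
        metrics_b$site_exchanges, "exchanges"))
  names(out)[2:3] <- labels
  out
}
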