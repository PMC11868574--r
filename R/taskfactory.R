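# Volunteer-computing task protocol at desk scale: tasks from
# conformations, atom-count volume estimation, a file-based message broker
# with atomic claim semantics, redundant-result verification, and a worker
# loop around a pluggable calculator.

#' Task-project configuration
#'
#' @param min_per_task,max_per_task Examples per task (single-conformation
#'   tasks: both 1).
#' @param properties Character vector naming the properties to calculate.
#' @param verification_threshold Relative tolerance for accepting a
#'   redundant result pair.
#' @param duplication Fraction of tasks re-issued for verification, in
#'   `[0, 1]`.
#' @return A `cf_project_config`.
#' @export
project_config <- function(min_per_task = 1, max_per_task = 1,
                           properties = "energy",
                           verification_threshold = 1e-3,
                           duplication = 0) {
  stopifnot(min_per_task <= max_per_task, verification_threshold > 0,
            duplication >= 0, duplication <= 1)
  structure(list(min_per_task = min_per_task, max_per_task = max_per_task,
                 properties = properties,
                 verification_threshold = verification_threshold,
                 duplication = duplication),
            class = "cf_project_config")
}

#' Task volume estimate
#'
#' The computational volume of a labeling task is estimated by the atom
#' count of its conformation (hydrogens included), which is invariant
#' across conformations of the same molecule.
#'
#' @param conf A `cf_conformation`.
#' @return Integer volume units.
#' @export
estimate_volume <- function(conf) {
  stopifnot(inherits(conf, "cf_conformation"))
  nrow(conf$coords)
}

#' Build labeling tasks from conformations
#'
#' One task per conformation; the task content is the conformation's V2000
#' MOL block (coordinates at 4 decimals). A `ceiling(duplication * n)`
#' prefix of the tasks is re-issued under fresh identifiers (suffix
#' `#dup`) for redundant-result verification.
#'
#' @param confs List of `cf_conformation`.
#' @param project A `cf_project_config`.
#' @param task_type Property-set tag carried on every task.
#' @return List of `cf_task` (`task_type`, `identifier`, `content`,
#'   `is_duplicate`).
#' @export
make_tasks <- function(confs, project = project_config(),
                       task_type = "conformational_energy") {
  stopifnot(length(confs) > 0)
  tasks <- lapply(confs, function(cf) {
    mol <- cf$molecule
    content <- tryCatch(
      .write_molblock(mol$atoms$symbol, cf$coords, mol$bonds,
                      title = paste0(mol$id, "/", cf$conf_id)),
      error = function(e) stop("cannot serialize conformation ",
                               mol$id, "/", cf$conf_id, ": ",
                               conditionMessage(e)))
    structure(list(task_type = task_type,
                   identifier = paste0(mol$id, "/", cf$conf_id),
                   content = content, is_duplicate = FALSE),
              class = "cf_task")
  })
  ids <- vapply(tasks, function(t) t$identifier, "")
  if (anyDuplicated(ids)) stop("task identifiers not unique")
  ndup <- ceiling(project$duplication * length(tasks))
  if (ndup > 0) {
    dups <- lapply(tasks[seq_len(ndup)], function(t) {
      t$identifier <- paste0(t$identifier, "#dup")
      t$is_duplicate <- TRUE
      t
    })
    tasks <- c(tasks, dups)
  }
  tasks
}

#' Parse a task's MOL-block content back into a conformation
#'
#' @param task A `cf_task`.
#' @return A `cf_conformation` (coordinates at MOL-block precision).
#' @export
task_to_conformation <- function(task) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste0(task$content, "\n$$$$"), tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))[[1]]
  can <- .ob_convert("SDF", "CAN", paste0(task$content, "\n$$$$\n"))
  can <- trimws(strsplit(can, "[\t\n]")[[1]][1])
  mol <- .molecule_from_sdf(sdf, sub("#dup$", "", task$identifier), can)
  ab <- ChemmineR::atomblock(sdf)
  conformation(mol, unname(ab[, 1:3, drop = FALSE]), "task")
}

# ---- file-based message broker --------------------------------------------
#
# Spool layout: pending/, claimed/, done/, failed/, quarantine/ with one
# JSON file per message, filename = zero-padded sequence + identifier.
# Claims are atomic file renames within one filesystem, so no two workers
# can obtain the same message; a timeout sweep returns stuck claims to
# pending.

.spool_dirs <- c("pending", "claimed", "done", "failed", "quarantine")

#' Initialize (or open) a broker spool directory
#' @param spool_dir Spool root path.
#' @return `spool_dir`, invisibly.
#' @export
broker_init <- function(spool_dir) {
  for (d in .spool_dirs) {
    dir.create(file.path(spool_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  invisible(spool_dir)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)

#' Enqueue a task on the broker
#'
#' Appends one message file to `pending/`, named by a zero-padded
#' sequence number (FIFO order) plus the task identifier.
#'
#' @param spool_dir Spool root.
#' @param task A `cf_task` (or any list with `task_type`, `identifier`,
#'   `content`).
#' @return The message filename, invisibly.
#' @export
broker_enqueue <- function(spool_dir, task) {
  broker_init(spool_dir)
  seqfile <- file.path(spool_dir, ".seq")
  n <- if (file.exists(seqfile)) {
    as.integer(readLines(seqfile, warn = FALSE)[1])
  } else 0L
  n <- n + 1L
  writeLines(as.character(n), seqfile)
  fname <- sprintf("%012d_%s.json", n, .safe_name(task$identifier))
  msg <- list(task_type = task$task_type, identifier = task$identifier,
              content = task$content, seq = n,
              enqueued_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  tmp <- file.path(spool_dir, paste0(".tmp_", fname))
  jsonlite::write_json(msg, tmp, auto_unbox = TRUE)
  file.rename(tmp, file.path(spool_dir, "pending", fname))
  invisible(fname)
}

#' Claim the oldest pending message
#'
#' Atomically moves one message from `pending/` to `claimed/` (rename on
#' one filesystem), so each message is claimed at most once even under
#' concurrent workers. Corrupt message files are quarantined and skipped.
#'
#' @param spool_dir Spool root.
#' @return A receipt (`message`, `file`) or `NULL` when the queue is
#'   empty.
#' @export
broker_claim <- function(spool_dir) {
  pending <- file.path(spool_dir, "pending")
  repeat {
    files <- sort(list.files(pending))
    if (length(files) == 0) return(NULL)
    got <- NULL
    for (f in files) {
      dst <- file.path(spool_dir, "claimed", f)
      ok <- suppressWarnings(file.rename(file.path(pending, f), dst))
      if (isTRUE(ok)) { got <- f; break }
    }
    if (is.null(got)) next  # lost every race; rescan
    msg <- tryCatch(jsonlite::read_json(file.path(spool_dir, "claimed", got)),
                    error = function(e) NULL)
    if (is.null(msg)) {
      file.rename(file.path(spool_dir, "claimed", got),
                  file.path(spool_dir, "quarantine", got))
      message("quarantined corrupt message: ", got)
      next
    }
    return(list(message = msg, file = got))
  }
}

#' Complete (or fail) a claimed message
#'
#' `broker_complete` attaches the result mapping and moves the message to
#' `done/`; `broker_fail` records the error and moves it to `failed/`.
#'
#' @param spool_dir Spool root.
#' @param receipt A receipt from [broker_claim()].
#' @param results Named list of finite numeric property values.
#' @return The message filename, invisibly.
#' @export
broker_complete <- function(spool_dir, receipt, results) {
  stopifnot(is.list(results))
  if (!all(vapply(results, function(v) is.numeric(v) && all(is.finite(v)),
                  TRUE))) {
    stop("task results must be finite numbers")
  }
  msg <- receipt$message
  msg$results <- results
  src <- file.path(spool_dir, "claimed", receipt$file)
  dst <- file.path(spool_dir, "done", receipt$file)
  jsonlite::write_json(msg, src, auto_unbox = TRUE, digits = NA)
  file.rename(src, dst)
  invisible(receipt$file)
}

#' @rdname broker_complete
#' @param error Error description string.
#' @export
broker_fail <- function(spool_dir, receipt, error) {
  msg <- receipt$message
  msg$error <- as.character(error)
  src <- file.path(spool_dir, "claimed", receipt$file)
  dst <- file.path(spool_dir, "failed", receipt$file)
  jsonlite::write_json(msg, src, auto_unbox = TRUE)
  file.rename(src, dst)
  invisible(receipt$file)
}

#' Return stale claims to the pending queue
#'
#' Claimed messages older than `timeout` seconds (by file modification
#' time) are assumed lost to a crashed worker and are re-queued.
#'
#' @param spool_dir Spool root.
#' @param timeout Seconds (default 30 minutes).
#' @return Number of re-queued messages.
#' @export
broker_requeue_stale <- function(spool_dir, timeout = 1800) {
  claimed <- file.path(spool_dir, "claimed")
  files <- list.files(claimed)
  n <- 0L
  for (f in files) {
    age <- as.numeric(difftime(Sys.time(),
                               file.mtime(file.path(claimed, f)),
                               units = "secs"))
    if (isTRUE(age > timeout)) {
      file.rename(file.path(claimed, f), file.path(spool_dir, "pending", f))
      n <- n + 1L
    }
  }
  n
}

#' Broker spool census
#' @param spool_dir Spool root.
#' @return Named counts per state.
#' @export
broker_status <- function(spool_dir) {
  vapply(.spool_dirs, function(d)
    length(list.files(file.path(spool_dir, d))), 0L)
}

#' Verify a redundant result pair
#'
#' Accepts when every shared property agrees within the project's
#' verification threshold (relative difference; absolute for magnitudes
#' below 1e-8). Mismatched property sets are rejected outright.
#'
#' @param primary,duplicate `TaskResult`-like lists with `task_type` and
#'   `results` (named numeric values).
#' @param cfg A `cf_project_config`.
#' @return List `accept` (logical) and `reason`.
#' @export
verify_result <- function(primary, duplicate, cfg = project_config()) {
  if (!identical(primary$task_type, duplicate$task_type)) {
    return(list(accept = FALSE, reason = "task_type mismatch"))
  }
  p <- primary$results; d <- duplicate$results
  if (!setequal(names(p), names(d))) {
    return(list(accept = FALSE, reason = "property-set mismatch"))
  }
  for (k in names(p)) {
    a <- as.numeric(p[[k]]); b <- as.numeric(d[[k]])
    scale <- max(abs(a), abs(b))
    diff <- if (scale < 1e-8) abs(a - b) else abs(a - b) / scale
    if (diff > cfg$verification_threshold) {
      return(list(accept = FALSE,
                  reason = sprintf("property '%s' differs (%.3g)", k, diff)))
    }
  }
  list(accept = TRUE, reason = "agreement within threshold")
}

#' Toy-oracle calculator for workers
#'
#' @param params A `cf_oracle_params`.
#' @return Function mapping a MOL-block string to
#'   `list(energy = <kcal/mol>)`.
#' @export
toy_calculator <- function(params = toy_oracle_params()) {
  function(molblock) {
    cf <- task_to_conformation(list(content = molblock, identifier = "task"))
    list(energy = toy_oracle(cf, params)$energy)
  }
}

#' Run a worker loop against a broker spool
#'
#' Claims, computes and completes up to `max_tasks` messages. A
#' calculator error fails that task only; the loop continues.
#'
#' @param spool_dir Spool root.
#' @param calculator Function mapping a MOL-block string to a named list
#'   of numeric property values.
#' @param max_tasks Upper bound on processed tasks.
#' @return Completion report: counts of `done` and `failed`, plus the
#'   processed identifiers in completion order.
#' @export
worker_loop <- function(spool_dir, calculator, max_tasks = Inf) {
  done <- character(0); failed <- character(0)
  while (length(done) + length(failed) < max_tasks) {
    receipt <- broker_claim(spool_dir)
    if (is.null(receipt)) break
    res <- tryCatch(calculator(receipt$message$content),
                    error = function(e) e)
    if (inherits(res, "error")) {
      broker_fail(spool_dir, receipt, conditionMessage(res))
      failed <- c(failed, receipt$message$identifier)
    } else {
      broker_complete(spool_dir, receipt, res)
      done <- c(done, receipt$message$identifier)
    }
  }
  list(done = length(done), failed = length(failed),
       done_ids = done, failed_ids = failed)
}
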