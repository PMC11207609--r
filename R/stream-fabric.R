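# In-memory topic/partition stream fabric.
#
# Each device category maps to one topic; topics are sharded into partitions
# distributed over cluster nodes. Initial placement is round-robin (perfect
# balance); when a node fails, only its partitions are re-placed, by
# rendezvous (highest-random-weight) hashing over the surviving nodes, which
# keeps reassignment churn minimal. Message durability across failures is
# assumed (replication abstraction): the fabric guarantees routing
# conservation, not byte-level replication.

TOPIC_ABBREV <- c(
  patient_monitor = "PM", ventilator = "VEN", hemodynamics_monitor = "HD",
  infusion_pump = "IP", hematology_analyzer = "HA", his = "HIS", ai = "AI"
)

hash_u32 <- function(x) {
  vapply(x, function(s) strtoi(substr(rlang::hash(s), 1, 7), 16L), 0)
}

#' Create topic specs for device categories
#'
#' One topic per category, named `Topic_<ABBREV>` (PM, VEN, HD, IP, HA, HIS,
#' AI; unknown categories are upper-cased).
#'
#' @param categories Character vector of unique device categories.
#' @param partitions Partitions per topic.
#' @return A tibble with columns `name`, `category`, `partitions`.
#' @examples
#' create_topics(c("patient_monitor", "ventilator"))
#' @export
create_topics <- function(categories, partitions = 64L) {
  if (length(categories) == 0L) {
    stop_icufusion("categories must be non-empty", "icufusion_validation_error")
  }
  if (anyDuplicated(categories) > 0) {
    stop_icufusion("categories must be unique", "icufusion_validation_error")
  }
  stopifnot(partitions >= 1L)
  abbrev <- purrr::map_chr(tolower(categories), function(cat) {
    TOPIC_ABBREV[[cat]] %||% toupper(gsub("[^[:alnum:]]", "", cat))
  })
  tibble::tibble(
    name = paste0("Topic_", abbrev),
    category = categories,
    partitions = as.integer(partitions)
  )
}

#' Build an in-memory broker cluster
#'
#' @param n_nodes Number of broker nodes (>= 1).
#' @param topics Topic tibble from [create_topics()].
#' @return An `icu_cluster` object holding node states, the partition
#'   assignment, and an (initially empty) message store.
#' @export
make_cluster <- function(n_nodes, topics) {
  stopifnot(n_nodes >= 1, nrow(topics) >= 1)
  nodes <- tibble::tibble(
    node_id = paste0("node-", seq_len(n_nodes)),
    live = TRUE
  )
  assignment <- tidyr::expand_grid(
    topic = topics$name,
    partition = seq_len(topics$partitions[1])
  )
  # round-robin initial placement: perfectly balanced and deterministic
  assignment$node_id <- nodes$node_id[
    (seq_len(nrow(assignment)) - 1L) %% n_nodes + 1L
  ]
  structure(
    list(
      nodes = nodes, topics = topics, assignment = assignment,
      messages = tibble::tibble(
        topic = character(), partition = integer(),
        key = character(), payload = character()
      ),
      down = FALSE
    ),
    class = "icu_cluster"
  )
}

#' @export
print.icu_cluster <- function(x, ...) {
  cat(
    "<icu_cluster>", sum(x$nodes$live), "of", nrow(x$nodes), "nodes live,",
    nrow(x$topics), "topics,", nrow(x$messages), "queued messages\n"
  )
  invisible(x)
}

partition_of <- function(key, topic_name, cluster) {
  p <- cluster$topics$partitions[cluster$topics$name == topic_name]
  if (length(p) == 0L) {
    stop_icufusion(paste0("unknown topic '", topic_name, "'"),
      "icufusion_validation_error")
  }
  (hash_u32(key) %% p) + 1L
}

rendezvous_node <- function(key, node_ids) {
  node_ids[which.max(hash_u32(paste0(key, "\r", node_ids)))]
}

#' Route a message key to a cluster node
#'
#' Deterministic for a fixed key and live-node set: the key hashes to a
#' partition and the partition's assigned node is returned. Over uniformly
#' random keys the load is balanced across live nodes.
#'
#' @param key Message key string.
#' @param topic Topic name.
#' @param cluster An `icu_cluster`.
#' @return The node id (with the partition index as attribute `partition`).
#' @export
assign_partition <- function(key, topic, cluster) {
  if (cluster$down || !any(cluster$nodes$live)) {
    stop_icufusion("no live nodes in cluster", "icufusion_cluster_down")
  }
  part <- partition_of(key, topic, cluster)
  node <- cluster$assignment$node_id[
    cluster$assignment$topic == topic & cluster$assignment$partition == part
  ]
  structure(node, partition = part)
}

#' Enqueue a message into the fabric
#'
#' @param cluster An `icu_cluster`.
#' @param topic Topic name.
#' @param key Message key (drives partition routing).
#' @param payload Message payload string.
#' @return The updated cluster.
#' @export
enqueue <- function(cluster, topic, key, payload) {
  node <- assign_partition(key, topic, cluster) # errors if cluster down
  cluster$messages <- dplyr::bind_rows(
    cluster$messages,
    tibble::tibble(
      topic = topic, partition = attr(node, "partition"),
      key = key, payload = payload
    )
  )
  cluster
}

#' Fail a broker node and reroute its partitions
#'
#' Partitions previously assigned to the failed node are re-placed by
#' rendezvous hashing over the surviving live nodes, so no partition is ever
#' unmapped while at least one node lives. Queued messages survive (the
#' replication abstraction). Failing the last live node flags the cluster as
#' down.
#'
#' @param cluster An `icu_cluster`.
#' @param node_id Node to fail; must exist and be live.
#' @return The updated cluster.
#' @export
fail_node <- function(cluster, node_id) {
  idx <- match(node_id, cluster$nodes$node_id)
  if (is.na(idx)) {
    stop_icufusion(paste0("unknown node '", node_id, "'"),
      "icufusion_validation_error")
  }
  if (!cluster$nodes$live[idx]) {
    stop_icufusion(paste0("node '", node_id, "' is already failed"),
      "icufusion_validation_error")
  }
  cluster$nodes$live[idx] <- FALSE
  live <- cluster$nodes$node_id[cluster$nodes$live]
  if (length(live) == 0L) {
    cluster$down <- TRUE
    return(cluster)
  }
  orphaned <- cluster$assignment$node_id == node_id
  if (any(orphaned)) {
    cluster$assignment$node_id[orphaned] <- purrr::map_chr(
      paste0(
        cluster$assignment$topic[orphaned], "#",
        cluster$assignment$partition[orphaned]
      ),
      rendezvous_node,
      node_ids = live
    )
  }
  cluster
}

#' Drain all queued messages
#'
#' Delivers every queued message (in enqueue order) and empties the store.
#' Message conservation holds under any failure schedule that leaves at
#' least one live node.
#'
#' @param cluster An `icu_cluster`.
#' @return A list with `messages` (tibble of delivered messages) and
#'   `cluster` (the drained cluster).
#' @export
drain <- function(cluster) {
  if (cluster$down) {
    stop_icufusion("cluster is down; nothing can be delivered",
      "icufusion_cluster_down")
  }
  delivered <- cluster$messages
  cluster$messages <- cluster$messages[0, ]
  list(messages = delivered, cluster = cluster)
}

#' The modeled ICU device inventory
#'
#' Unit counts, per-category data rates and yearly storage of the five
#' modeled device categories (patient monitors, ventilators, hemodynamics
#' monitors, infusion pumps, hematology analyzers).
#'
#' @return A tibble with columns `category`, `units`, `rate`, `rate_unit`,
#'   `storage`, `storage_unit`.
#' @export
icu_device_inventory <- function() {
  tibble::tibble(
    category = c(
      "patient_monitor", "ventilator", "hemodynamics_monitor",
      "infusion_pump", "hematology_analyzer"
    ),
    units = c(470, 180, 20, 500, 30),
    rate = c(29.7, 26.1, 2.32, 344, 7.2),
    rate_unit = c("Mbps", "Mbps", "Mbps", "Kbps", "Mbps"),
    storage = c(8.7, 11.3, 630, 1.1, 6.8),
    storage_unit = c("TB", "TB", "GB", "TB", "GB")
  )
}

#' Aggregate stream inventory into net data rate and storage
#'
#' Sums per-category data rates and storage with decimal unit normalization
#' (1 Mbps = 1000 Kbps, 1 TB = 1000 GB). Aggregation is an exact,
#' order-independent sum.
#'
#' @param inventory Inventory tibble, see [icu_device_inventory()].
#' @return A one-row tibble: `total_mbps`, `total_mbps_rounded` (2 decimals),
#'   `total_tb_per_year`, `total_tb_rounded` (nearest TB).
#' @examples
#' aggregate_stream_stats(icu_device_inventory())
#' @export
aggregate_stream_stats <- function(inventory) {
  if (nrow(inventory) == 0L) {
    return(tibble::tibble(
      total_mbps = 0, total_mbps_rounded = 0,
      total_tb_per_year = 0, total_tb_rounded = 0
    ))
  }
  if (any(inventory$rate < 0) || any(inventory$storage < 0)) {
    stop_icufusion("rates and storage must be non-negative",
      "icufusion_validation_error")
  }
  bad_units <- setdiff(inventory$rate_unit, c("Mbps", "Kbps")) |>
    c(setdiff(inventory$storage_unit, c("TB", "GB")))
  if (length(bad_units) > 0) {
    stop_icufusion(paste0("unknown units: ", toString(bad_units)),
      "icufusion_validation_error")
  }
  mbps <- sum(inventory$rate / ifelse(inventory$rate_unit == "Kbps", 1000, 1))
  tb <- sum(inventory$storage / ifelse(inventory$storage_unit == "GB", 1000, 1))
  tibble::tibble(
    total_mbps = mbps, total_mbps_rounded = round(mbps, 2),
    total_tb_per_year = tb, total_tb_rounded = round(tb)
  )
}

#' Discrete-event estimate of mean broker delay
#'
#' Simulates Poisson message arrivals over `n_topics` topics, uniform
#' key-hash routing to `n_nodes` nodes, and exponential service at each node
#' (a fork of M/M/1 queues via the Lindley recursion). Returns the mean
#' sojourn (queueing + service) time with a batch-means standard error; the
#' expectation is monotone non-increasing in `n_nodes`. At `n_nodes = 1` the
#' estimate agrees with the M/M/1 closed form `1 / (mu - lambda)`.
#'
#' @param n_nodes Number of broker nodes.
#' @param n_topics Number of topics.
#' @param arrival_rate Per-topic Poisson arrival rate (messages per unit
#'   time).
#' @param service_rate Per-node exponential service rate `mu`.
#' @param n_messages Number of arrivals to simulate.
#' @param seed RNG seed.
#' @param n_batches Batches for the batch-means standard error.
#' @return A one-row tibble: `n_nodes`, `n_topics`, `mean_delay`, `se`,
#'   `utilization`, `n_messages`.
#' @export
simulate_delay <- function(n_nodes, n_topics, arrival_rate, service_rate,
                           n_messages = 20000L, seed = 1L, n_batches = 20L) {
  stopifnot(n_nodes >= 1, n_topics >= 1, arrival_rate > 0, service_rate > 0)
  lambda_tot <- n_topics * arrival_rate
  rho <- lambda_tot / (n_nodes * service_rate)
  if (rho >= 1) {
    stop_icufusion(
      sprintf("unstable configuration: utilization %.3f >= 1", rho),
      "icufusion_unstable"
    )
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  arrivals <- cumsum(stats::rexp(n_messages, rate = lambda_tot))
  node <- sample.int(n_nodes, n_messages, replace = TRUE)
  service <- stats::rexp(n_messages, rate = service_rate)
  sojourn <- numeric(n_messages)
  for (k in seq_len(n_nodes)) {
    sel <- which(node == k)
    if (length(sel) == 0L) next
    a <- arrivals[sel]
    s <- service[sel]
    d <- numeric(length(sel))
    prev <- 0
    for (j in seq_along(sel)) {
      prev <- max(a[j], prev) + s[j]
      d[j] <- prev
    }
    sojourn[sel] <- d - a
  }
  batch <- cut(seq_len(n_messages), breaks = n_batches, labels = FALSE)
  bm <- tapply(sojourn, batch, mean)
  tibble::tibble(
    n_nodes = n_nodes, n_topics = n_topics,
    mean_delay = mean(sojourn),
    se = stats::sd(bm) / sqrt(length(bm)),
    utilization = rho, n_messages = n_messages
  )
}

#' Delay profile over cluster sizes
#'
#' Convenience wrapper running [simulate_delay()] for each cluster size; the
#' result feeds [plot_delay_profile()].
#'
#' @param n_nodes_seq Integer vector of cluster sizes.
#' @inheritParams simulate_delay
#' @return A tibble with one row per cluster size.
#' @export
delay_profile <- function(n_nodes_seq, n_topics, arrival_rate, service_rate,
                          n_messages = 20000L, seed = 1L) {
  purrr::map(n_nodes_seq, function(n) {
    simulate_delay(n, n_topics, arrival_rate, service_rate,
      n_messages = n_messages, seed = seed
    )
  }) |> dplyr::bind_rows()
}

# Saving/restoring .Random.seed keeps simulators from clobbering the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
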