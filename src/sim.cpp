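#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Agent-based two-population Brownian simulation on a square-cell lattice.
// Shared update rule (one step): population transitions first, then a
// Gaussian displacement; in topology mode constrained agents are folded back
// into their home cell by exact specular reflection (triangle-wave fold).
// Uses R's RNG so results are reproducible under set.seed().

static inline double fold_axis(double u, double L) {
  double p = 2.0 * L;
  double m = u - p * std::floor(u / p);   // remainder in [0, 2L)
  return L - std::fabs(m - L);
}

struct Agent {
  double x, y;
  bool free_state;
  int layer;       // meaningful for constrained agents in bilayers
  double hx, hy;   // home-cell lower-left corner (constrained only)
};

static inline double layer_off(int layer, int arrangement, double L) {
  // arrangement: 0 monolayer, 1 stacked bilayer, 2 offset bilayer
  return (arrangement == 2 && layer == 1) ? 0.5 * L : 0.0;
}

static inline void bind_here(Agent &a, int arrangement, double L) {
  a.layer = (arrangement == 0) ? 0 : (unif_rand() < 0.5 ? 0 : 1);
  double off = layer_off(a.layer, arrangement, L);
  a.hx = off + L * std::floor((a.x - off) / L);
  a.hy = off + L * std::floor((a.y - off) / L);
}

// One simulation step for an agent; returns false if it hit the extent.
static inline bool step_agent(Agent &a, double sd_free, double sd_con,
                              double p_fc, double p_cf, double L,
                              bool topology, int arrangement,
                              double max_coord) {
  double u = unif_rand();
  if (a.free_state) {
    if (u < p_fc) { a.free_state = false; bind_here(a, arrangement, L); }
  } else {
    if (u < p_cf) a.free_state = true;
  }
  double sd = a.free_state ? sd_free : sd_con;
  double xp = a.x + norm_rand() * sd;
  double yp = a.y + norm_rand() * sd;
  if (!a.free_state && topology) {
    xp = a.hx + fold_axis(xp - a.hx, L);
    yp = a.hy + fold_axis(yp - a.hy, L);
  }
  a.x = xp; a.y = yp;
  return std::fabs(xp) < max_coord && std::fabs(yp) < max_coord;
}

// [[Rcpp::export]]
List cpp_msd_protocol(int n_agents, int n_steps, double dt,
                      double D_free, double D_con,
                      double p_fc, double p_cf,
                      double L, bool topology, int arrangement,
                      double init_free_frac, int extent,
                      int thin, int n_groups) {
  RNGScope scope;
  std::vector<Agent> agents(n_agents);
  for (int i = 0; i < n_agents; ++i) {
    Agent &a = agents[i];
    a.x = unif_rand() * L;
    a.y = unif_rand() * L;
    a.free_state = unif_rand() < init_free_frac;
    a.layer = 0; a.hx = 0.0; a.hy = 0.0;  // sender cell (0,0), layer 0
  }
  double sd_free = std::sqrt(2.0 * D_free * dt);
  double sd_con  = std::sqrt(2.0 * D_con * dt);
  double cx = 0.5 * L, cy = 0.5 * L;
  double max_coord = (double)extent * L;

  int n_rec = n_steps / thin;
  NumericVector time_s(n_rec);
  NumericVector msd(n_rec);
  NumericMatrix group_msd(n_rec, n_groups);
  IntegerVector group_n(n_groups);
  for (int i = 0; i < n_agents; ++i) group_n[i % n_groups]++;

  int rec = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n_agents; ++i) {
      if (!step_agent(agents[i], sd_free, sd_con, p_fc, p_cf, L,
                      topology, arrangement, max_coord))
        stop("an agent reached the lattice extent; enlarge extent_cells");
    }
    if (s % thin == 0) {
      std::vector<double> gsum(n_groups, 0.0);
      double tot = 0.0;
      for (int i = 0; i < n_agents; ++i) {
        double dx = agents[i].x - cx, dy = agents[i].y - cy;
        double r2 = dx * dx + dy * dy;
        gsum[i % n_groups] += r2;
        tot += r2;
      }
      time_s[rec] = s * dt;
      msd[rec] = tot / n_agents;
      for (int g = 0; g < n_groups; ++g)
        group_msd(rec, g) = gsum[g] / group_n[g];
      ++rec;
    }
  }
  NumericVector fx(n_agents), fy(n_agents);
  for (int i = 0; i < n_agents; ++i) { fx[i] = agents[i].x; fy[i] = agents[i].y; }
  return List::create(_["time_s"] = time_s, _["msd"] = msd,
                      _["group_msd"] = group_msd, _["group_n"] = group_n,
                      _["final_x"] = fx, _["final_y"] = fy);
}

// [[Rcpp::export]]
List cpp_flux_protocol(int source_count, int n_steps, double dt,
                       double D_free, double D_con,
                       double p_fc, double p_cf,
                       double L, bool topology, int arrangement,
                       double init_free_frac, int extent, int thin) {
  RNGScope scope;
  double sd_free = std::sqrt(2.0 * D_free * dt);
  double sd_con  = std::sqrt(2.0 * D_con * dt);
  double max_coord = (double)extent * L;

  auto fresh_agent = [&]() {
    Agent a;
    a.x = unif_rand() * L;
    a.y = unif_rand() * L;
    a.free_state = unif_rand() < init_free_frac;
    a.layer = 0; a.hx = 0.0; a.hy = 0.0;
    return a;
  };
  auto in_sender = [&](const Agent &a) {
    // topology-mode constrained agents belong to their home cell; everyone
    // else is judged by position against the sender footprint [0,L)^2
    if (topology && !a.free_state)
      return a.hx == 0.0 && a.hy == 0.0 && a.layer == 0;
    return a.x >= 0.0 && a.x < L && a.y >= 0.0 && a.y < L;
  };

  std::vector<Agent> sender;
  sender.reserve(source_count);
  for (int i = 0; i < source_count; ++i) sender.push_back(fresh_agent());
  std::vector<Agent> field;
  field.reserve(4 * source_count);

  int n_rec = n_steps / thin;
  NumericVector time_s(n_rec);
  NumericVector field_count(n_rec);
  int rec = 0;

  for (int s = 1; s <= n_steps; ++s) {
    // advance field molecules; delete those re-entering the sender cell
    for (size_t i = 0; i < field.size();) {
      if (!step_agent(field[i], sd_free, sd_con, p_fc, p_cf, L,
                      topology, arrangement, max_coord))
        stop("an agent reached the lattice extent; enlarge extent_cells");
      if (in_sender(field[i])) {
        field[i] = field.back();
        field.pop_back();
      } else {
        ++i;
      }
    }
    // advance sender-resident molecules; emigrants join the field
    for (size_t i = 0; i < sender.size();) {
      if (!step_agent(sender[i], sd_free, sd_con, p_fc, p_cf, L,
                      topology, arrangement, max_coord))
        stop("an agent reached the lattice extent; enlarge extent_cells");
      if (!in_sender(sender[i])) {
        field.push_back(sender[i]);
        sender[i] = sender.back();
        sender.pop_back();
      } else {
        ++i;
      }
    }
    // top the sender back up to its constant occupancy
    while ((int)sender.size() < source_count) sender.push_back(fresh_agent());
    if (s % thin == 0) {
      time_s[rec] = s * dt;
      field_count[rec] = (double)field.size();
      ++rec;
    }
  }
  return List::create(_["time_s"] = time_s, _["field_count"] = field_count);
}
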