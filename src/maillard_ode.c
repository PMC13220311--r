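/* Mass-action right-hand side for deSolve, shared by all network variants.
 *
 * The network structure (reactant indices, stoichiometry) and the rate
 * constants are pushed from R via mr_ode_setup() before each integration;
 * deSolve then calls mr_derivs() by symbol.  Static storage bounds the
 * network size; the R side validates against these limits.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MR_MAX_SPEC 128
#define MR_MAX_STEP 128

static int n_spec = 0, n_steps = 0;
static int r1[MR_MAX_STEP], r2[MR_MAX_STEP];
static double kval[MR_MAX_STEP];
static double stoich[MR_MAX_SPEC * MR_MAX_STEP]; /* species x steps, column-major */

SEXP mr_ode_setup(SEXP nspec_, SEXP k_, SEXP r1_, SEXP r2_, SEXP S_)
{
    int ns = Rf_asInteger(nspec_);
    int nr = LENGTH(k_);
    if (ns < 1 || ns > MR_MAX_SPEC || nr < 1 || nr > MR_MAX_STEP)
        Rf_error("network exceeds compiled solver limits (%d species, %d steps)",
                 MR_MAX_SPEC, MR_MAX_STEP);
    if (LENGTH(r1_) != nr || LENGTH(r2_) != nr || LENGTH(S_) != ns * nr)
        Rf_error("inconsistent network encoding");
    n_spec = ns;
    n_steps = nr;
    double *k = REAL(k_), *S = REAL(S_);
    int *a = INTEGER(r1_), *b = INTEGER(r2_);
    for (int j = 0; j < nr; j++) {
        kval[j] = k[j];
        r1[j] = a[j] - 1;
        r2[j] = b[j] - 1; /* -1 encodes a unimolecular step */
    }
    for (int i = 0; i < ns * nr; i++) stoich[i] = S[i];
    return R_NilValue;
}

void mr_derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    for (int i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (int j = 0; j < n_steps; j++) {
        double v = kval[j] * y[r1[j]];
        if (r2[j] >= 0) v *= y[r2[j]];
        if (v == 0.0) continue;
        const double *col = stoich + (size_t)j * n_spec;
        for (int i = 0; i < n_spec; i++)
            if (col[i] != 0.0) ydot[i] += col[i] * v;
    }
}

static const R_CallMethodDef call_entries[] = {
    {"mr_ode_setup", (DL_FUNC) &mr_ode_setup, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"mr_derivs", (DL_FUNC) &mr_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_maillardkin(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks the RHS up by name */
}
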