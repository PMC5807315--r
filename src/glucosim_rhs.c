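/* Compiled right-hand side of the 19-variable glucose-flux ODE system for
 * deSolve (initfunc = "glucosim_initmod", func = "glucosim_derivs").
 * Parameter order must match parameter_names(); state order state_names().
 * Negative components are clipped to zero locally so the derivative stays
 * defined if the solver steps slightly below zero (the 11th power in R17
 * amplifies tiny negative excursions).
 */
#include <R.h>
#include <math.h>

static double parms[40];
#define k0 parms[0]
#define k1 parms[1]
#define k_m1 parms[2]
#define k2 parms[3]
#define k_m2 parms[4]
#define k3 parms[5]
#define k_m3 parms[6]
#define k4 parms[7]
#define k_m4 parms[8]
#define k5 parms[9]
#define k_m5 parms[10]
#define k_m6 parms[11]
#define k_as parms[12]
#define k_mas parms[13]
#define k_am parms[14]
#define k_mam parms[15]
#define k_al parms[16]
#define k_mal parms[17]
#define k_g parms[18]
#define k_mg parms[19]
#define k_d parms[20]
#define k_md parms[21]
#define k_p parms[22]
#define k_s parms[23]
#define k_f parms[24]
#define delta_p parms[25]
#define delta_s parms[26]
#define delta_f parms[27]
#define c2 parms[28]
#define c_m2 parms[29]
#define c_m6 parms[30]
#define c_md parms[31]
#define e2 parms[32]
#define e_m2 parms[33]
#define e_m6 parms[34]
#define e_md parms[35]
#define alpha parms[36]
#define K1 parms[37]
#define K2 parms[38]
#define K3 parms[39]

void glucosim_initmod(void (*odeparms)(int *, double *)) {
  int n = 40;
  odeparms(&n, parms);
}

void glucosim_derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip) {
  double s[19];
  for (int i = 0; i < 19; i++) s[i] = y[i] < 0 ? 0 : y[i];
  double S1=s[0],S2=s[1],S3=s[2],S4=s[3],S5=s[4],S6=s[5],S7=s[6];
  double E1=s[7],E2=s[8],E3=s[9],E4=s[10],ES=s[11],EM=s[12],EL=s[13],E3s=s[14],E1g=s[15];
  double P1=s[16],P2=s[17],P3=s[18];
  double R1=k0, R2=k1*S1, R3=k_m1*S2;
  double R4=k2*(E1+ES+c2*EM+e2*EL)*S2*K1/(K1+S3);
  double R5=k_m2*(E2+c_m2*EM+e_m2*EL)*S3*K2/(K2+S2);
  double R6=k3*S3, R7=k_m3*S4, R8=k4*S4, R9=k_m4*S5;
  double R10=k5*E3s*S5, R11=k_m5*S6;
  double R12=k_m6*(E4+c_m6*EM+e_m6*EL)*S7;
  double R13=k_as*E1, R14=k_mas*ES, R15=k_am*ES*E2*E3*E4, R16=k_mam*EM;
  double R17=k_al*pow(EM,11.0), R18=k_mal*EL, R19=k_g*E1, R20=k_mg*E1g;
  double R21=k_d*E3s;
  double R22=k_md*(E3+c_md*EM+e_md*EL)*(1.0+alpha*S3/(S3+K3));
  double R23=k_p*S2, R24=k_s*S4, R25=k_f*S6;
  double R26=delta_p*P1, R27=delta_s*P2, R28=delta_f*P3;
  ydot[0]=R1-R2+R3;
  ydot[1]=R2-R3-R4+R5-R23;
  ydot[2]=R4-R5-R6+R7;
  ydot[3]=R6-R7-R8+R9-R24;
  ydot[4]=R8-R9-R10+R12;
  ydot[5]=R10-R11-R25;
  ydot[6]=R11-R12;
  ydot[7]=-R13+R14-R19+R20;
  ydot[8]=-R15+R16;
  ydot[9]=-R15+R16+R21-R22;
  ydot[10]=-R15+R16;
  ydot[11]=R13-R14-R15+R16;
  ydot[12]=R15-R16-11.0*R17+11.0*R18;
  ydot[13]=R17-R18;
  ydot[14]=-R21+R22;
  ydot[15]=R19-R20;
  ydot[16]=R23-R26;
  ydot[17]=R24-R27;
  ydot[18]=R25-R28;
}
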