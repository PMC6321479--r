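# synthetic far-UV CD reference basis (idealized class lineshapes)
# units: deg cm^2/dmol (mean residue ellipticity scale)
wavelength_nm,helix,sheet,turn,coil
190,56934,9125.7,-8951.6,-9218.7
191,62852.1,13127.6,-8662.3,-13147.4
192,64925.2,17676.2,-7888.8,-17882.3
193,62730.6,22277.6,-6723.3,-23196.2
194,56639.6,26279.8,-5294.5,-28695.5
195,47686.5,29015.6,-3732.8,-33853.1
196,37241.1,29982.7,-2142.3,-38084.7
197,26618.2,28991.7,-585.4,-40853.9
198,16770.9,26223.8,914.6,-41782.4
199,8158.2,22172.1,2358.8,-40732.3
200,794.7,17491.2,3751.5,-37837.2
201,-5579.2,12816.7,5081.6,-33471.6
202,-11290.7,8620.5,6312.8,-28168
203,-16568.1,5142.8,7383.8,-22508.2
204,-21453.2,2404.1,8219.1,-17017
205,-25799,269.9,8745.9,-12087.2
206,-29336.9,-1466.5,8911.5,-7946.3
207,-31781,-3013.9,8697.8,-4664.4
208,-32937.1,-4538.2,8126.7,-2190.8
209,-32783.4,-6141.5,7257.6,-401.7
210,-31504.4,-7859.7,6176.5,854
211,-29467.1,-9668.7,4980.7,1721.2
212,-27151.4,-11496.4,3763.3,2319.8
213,-25052.8,-13237.5,2600.1,2737.8
214,-23585.4,-14769.2,1543.2,3033.8
215,-23007,-15969.8,619.5,3243
216,-23381.4,-16736.4,-165.3,3384.5
217,-24581.4,-17000,-820.1,3467.6
218,-26326.2,-16736.4,-1361.5,3496.8
219,-28241.9,-15970,-1807,3474.5
220,-29931.2,-14769.9,-2171.6,3403.7
221,-31039.9,-13239.6,-2465.2,3287.8
222,-31309.3,-11502.8,-2693.3,3131.9
223,-30609.5,-9686.3,-2857.7,2942.2
224,-28946.9,-7905.7,-2958.1,2725.8
225,-26450.7,-6254,-2994.3,2490.5
226,-23340.3,-4795.1,-2967.6,2244.1
227,-19882.8,-3563.4,-2881.3,1994.2
228,-16348.5,-2566.6,-2741.3,1747.7
229,-12974,-1791.8,-2556.2,1510.6
230,-9936.8,-1212.4,-2336.3,1287.6
231,-7344.9,-795.1,-2093,1082.4
232,-5239.5,-505.4,-1837.9,897.3
233,-3607,-311.4,-1581.9,733.6
234,-2396.5,-185.9,-1334.6,591.5
235,-1536.6,-107.6,-1103.6,470.4
236,-950.8,-60.4,-894.6,368.9
237,-567.8,-32.8,-710.8,285.3
238,-327.2,-17.3,-553.6,217.6
239,-182,-8.8,-422.6,163.7
240,-97.7,-4.4,-316.2,121.4
241,-50.6,-2.1,-231.9,88.8
242,-25.3,-1,-166.7,64.1
243,-12.2,-0.4,-117.5,45.6
244,-5.7,-0.2,-81.2,32
245,-2.6,-0.1,-54.9,22.2
246,-1.1,0,-36.5,15.1
247,-0.5,0,-23.7,10.2
248,-0.2,0,-15.1,6.8
249,-0.1,0,-9.5,4.4
250,0,0,-5.8,2.9
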